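Package: memphys
Title: Physical Observables and Free-Energy Calculations for Lipid Bilayer Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the standard set of physical observables used to validate
    molecular-dynamics simulations of phospholipid bilayers: headgroup area per
    lipid and area compressibility modulus from box fluctuations, C-H bond
    orientational order parameters, transmembrane electron / charge / neutron
    scattering length density profiles, X-ray and neutron scattering form
    factors, and the membrane dipole potential.  Also implements the
    permeability workflow of the inhomogeneous solubility-diffusion model:
    umbrella-sampling potentials of mean force via the weighted histogram
    analysis method (WHAM), position-dependent diffusivity from the
    autocorrelation of harmonically restrained coordinates, and the
    permeability integral; plus staged thermodynamic-integration /
    free-energy-perturbation bookkeeping for solvation and transfer energies
    with a Weeks-Chandler-Andersen component split.  Includes readers and
    writers for PSF topologies and multi-model PDB / binary DCD trajectories,
    and a synthetic-data module that generates bilayer trajectories, Langevin
    umbrella windows and lambda-coupled free-energy samples with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
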