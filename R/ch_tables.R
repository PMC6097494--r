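# Packaged C-H pair tables for CHARMM36 phosphatidylcholines and their
# mapping onto a concrete topology.

#' Load a packaged C-H pair table
#'
#' Tables of (chain label, carbon atom name, hydrogen atom name) for the
#' CHARMM36 atom naming of DPPC and POPC: the sn-1/sn-2 acyl carbons and the
#' headgroup/glycerol sites (alpha, beta, g1, g2, g3).  Users may supply
#' their own table in the same three-column tab-separated format.
#'
#' @param lipid \code{"DPPC"} or \code{"POPC"}, or a path to a custom table.
#' @return data.frame with columns \code{chain_label},
#'   \code{carbon_atom_name}, \code{hydrogen_atom_name}.
#' @export
ch_pair_table <- function(lipid = c("DPPC", "POPC")) {
  path <- if (file.exists(lipid[1])) lipid[1] else {
    lipid <- match.arg(lipid)
    system.file("extdata",
                sprintf("ch_pairs_%s.tsv", tolower(lipid)),
                package = "memphys", mustWork = TRUE)
  }
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Map a C-H pair table onto a topology
#'
#' Expands the per-residue (carbon name, hydrogen name) table into concrete
#' atom-index pairs for every lipid residue of the topology, ready for
#' \code{\link{order_parameters}}.  Sites absent from the topology are
#' skipped silently (e.g. a DPPC table applied to a truncated fixture).
#'
#' @param top a \code{Topology}.
#' @param table a C-H pair table (see \code{\link{ch_pair_table}}).
#' @return data.frame with \code{label} (chain label, carbon name),
#'   \code{c_index}, \code{h_index} (1-based).
#' @export
ch_pairs_from_table <- function(top, table) {
  a <- top$atoms
  lip <- a$resname %in% top$lipid_residue_names
  if (!any(lip)) stop("topology has no lipid residues")
  res_key <- paste(a$segment, a$resid)
  out <- lapply(unique(res_key[lip]), function(rk) {
    rows <- which(res_key == rk)
    ci <- rows[match(table$carbon_atom_name, a$name[rows])]
    hi <- rows[match(table$hydrogen_atom_name, a$name[rows])]
    ok <- !is.na(ci) & !is.na(hi)
    if (!any(ok)) return(NULL)
    data.frame(label = paste(table$chain_label, table$carbon_atom_name)[ok],
               c_index = ci[ok], h_index = hi[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    stop("no C-H pairs of the table matched the topology's atom names")
  out
}
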