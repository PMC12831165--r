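#' Read atomic coordinates from a PDB file
#'
#' Thin wrapper over \pkg{bio3d}'s PDB reader returning a flat atom table.
#' Only the first model is retained; alternate locations are resolved by
#' keeping blank or `'A'` altloc records; HETATM records are excluded by
#' default (set `het = TRUE` to keep them).
#'
#' @param source path to a PDB-format file.
#' @param het keep HETATM records.
#' @return an object of class `structure_model`: a data.frame with columns
#'   `chain`, `resno`, `resid`, `elety` (atom name), `x`, `y`, `z`.
#' @export
read_pdb <- function(source, het = FALSE) {
  .check(file.exists(source), sprintf("file not found: %s", source))
  pdb <- tryCatch(bio3d::read.pdb(source, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  at <- pdb$atom
  .check(nrow(at) > 0, "no atoms in file")
  keep <- at$type == "ATOM" | (het & at$type == "HETATM")
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  .check(nrow(at) > 0, "no atoms left after model/altloc filtering")
  .check(all(is.finite(at$x)) && all(is.finite(at$y)) && all(is.finite(at$z)),
         "non-finite coordinates")
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  class(out) <- c("structure_model", "data.frame")
  out
}

#' Ligand residues contacting receptor chains
#'
#' A ligand residue is annotated as a contact when any of its atoms lies
#' within `cutoff` (inclusive: a distance of exactly 4.5 angstrom counts)
#' of any atom of any listed receptor chain. All atoms present in the model
#' are used (hydrogens included if deposited); pass `heavy_only = TRUE` to
#' exclude hydrogens.
#'
#' @param struct a `structure_model` from [read_pdb()].
#' @param ligand_chain chain identifier of the ligand.
#' @param receptor_chains character vector of receptor chain identifiers.
#' @param cutoff distance threshold in angstrom (default 4.5).
#' @param heavy_only drop hydrogen atoms first.
#' @return data.frame with one row per contacting ligand residue and
#'   partner chain: `resno`, `resid`, `partner_chain`, `min_distance`.
#' @export
contact_residues <- function(struct, ligand_chain, receptor_chains,
                             cutoff = 4.5, heavy_only = FALSE) {
  stopifnot(inherits(struct, "structure_model"))
  if (heavy_only) {
    struct <- struct[!grepl("^H|^[0-9]H", struct$elety), , drop = FALSE]
  }
  present <- unique(struct$chain)
  missing <- setdiff(c(ligand_chain, receptor_chains), present)
  .check(length(missing) == 0,
         sprintf("chain(s) not in structure: %s",
                 paste(missing, collapse = ", ")))
  lig <- struct[struct$chain == ligand_chain, , drop = FALSE]
  rows <- list()
  for (rc in receptor_chains) {
    rec <- struct[struct$chain == rc, , drop = FALSE]
    rxyz <- as.matrix(rec[, c("x", "y", "z")])
    for (rn in unique(lig$resno)) {
      res <- lig[lig$resno == rn, , drop = FALSE]
      lxyz <- as.matrix(res[, c("x", "y", "z")])
      # min over the all-pairs distance matrix between this residue's atoms
      # and every receptor-chain atom
      d2 <- outer(rowSums(lxyz^2), rowSums(rxyz^2), "+") -
        2 * lxyz %*% t(rxyz)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= cutoff) {
        rows[[length(rows) + 1L]] <-
          data.frame(resno = rn, resid = res$resid[1], partner_chain = rc,
                     min_distance = dmin, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(resno = integer(0), resid = character(0),
                      partner_chain = character(0),
                      min_distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' C-alpha distance between two chains' C-terminal residues
#'
#' The C-terminal residue of a chain is taken as its highest-numbered
#' residue possessing a CA atom in the selected model (deposited structures
#' often truncate true termini, so the residue numbers used are reported
#' alongside the distance).
#'
#' @param struct a `structure_model` from [read_pdb()].
#' @param chain_a,chain_b chain identifiers.
#' @return list with `distance` (angstrom), `resno_a`, `resno_b`.
#' @export
c_terminal_distance <- function(struct, chain_a, chain_b) {
  stopifnot(inherits(struct, "structure_model"))
  term_ca <- function(ch) {
    ca <- struct[struct$chain == ch & struct$elety == "CA", , drop = FALSE]
    .check(nrow(ca) > 0, sprintf("chain %s has no CA atoms", ch))
    ca[which.max(ca$resno), , drop = FALSE]
  }
  a <- term_ca(chain_a)
  b <- term_ca(chain_b)
  list(distance = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2),
       resno_a = a$resno, resno_b = b$resno)
}
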