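# Per-residue resolved-fraction and normalized B-factor profiles across an
# ensemble of crystal structures of the same kinase domain. A residue counts
# as "resolved" when its alpha-carbon has coordinates; missing density in a
# flexible loop shows up as a low presence fraction.

#' Read per-residue observations from PDB structures
#'
#' Parses each PDB file (via [bio3d::read.pdb()]) and reports, for every
#' residue number in `residue_range`, whether the residue is resolved (its
#' alpha-carbon is present in the selected chain) and the alpha-carbon
#' temperature factor when it is.
#'
#' @param files Character vector of PDB file paths. Structure identifiers are
#'   the file names without extension.
#' @param residue_range Integer vector of author residue numbers to report
#'   (BRAF kinase-domain numbering is taken verbatim; no renumbering).
#' @param chain_map Optional chain selection: either a single chain id
#'   applied to every structure, or a named character vector mapping
#'   structure id to chain. By default the first chain containing any residue
#'   of `residue_range` is used (crystals often carry several copies of the
#'   kinase domain; exactly one chain per structure is counted).
#' @return data.frame with columns `structure_id`, `chain`,
#'   `residue_number`, `amino_acid` (1-letter, `NA` when unresolved),
#'   `resolved` (logical) and `bfactor` (`NA` when unresolved).
#' @export
read_ensemble_residues <- function(files, residue_range,
                                   chain_map = NULL) {
  if (length(files) == 0L) stop("no PDB files supplied", call. = FALSE)
  out <- lapply(files, function(f) {
    id <- sub("\\.[^.]*$", "", basename(f))
    pdb <- tryCatch(bio3d::read.pdb(f, verbose = FALSE),
                    error = function(e) stop("failed to parse PDB file '", f,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    atoms <- pdb$atom[pdb$atom$elety == "CA" &
                        (pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM"), ]
    chain <- select_chain(atoms, residue_range, chain_map, id)
    atoms <- atoms[atoms$chain %in% chain, ]
    # drop alternate-location duplicates: keep the first CA per residue
    atoms <- atoms[!duplicated(atoms$resno), ]
    idx <- match(residue_range, atoms$resno)
    data.frame(
      structure_id = id,
      chain = chain,
      residue_number = as.integer(residue_range),
      amino_acid = ifelse(is.na(idx), NA_character_,
                          bio3d::aa321(atoms$resid[idx])),
      resolved = !is.na(idx),
      bfactor = ifelse(is.na(idx), NA_real_, atoms$b[idx]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

select_chain <- function(atoms, residue_range, chain_map, id) {
  if (!is.null(chain_map)) {
    chain <- if (!is.null(names(chain_map))) chain_map[[id]] else chain_map[[1L]]
    if (is.null(chain) || is.na(chain))
      stop("chain_map has no entry for structure '", id, "'", call. = FALSE)
    if (!chain %in% atoms$chain)
      stop("chain '", chain, "' not found in structure '", id, "'",
           call. = FALSE)
    return(chain)
  }
  hit <- atoms$chain[atoms$resno %in% residue_range]
  if (length(hit) == 0L)
    stop("no chain of structure '", id, "' contains residues in range",
         call. = FALSE)
  hit[1L]
}

#' Within-structure normalized B-factors
#'
#' Z-normalizes the alpha-carbon B-factors of each structure over its
#' resolved residues in the analysed range (mean 0, SD 1), making temperature
#' factors comparable across crystals with different overall mobility and
#' refinement. A structure whose resolved B-factors have zero variance
#' contributes 0 for all its residues (with a warning).
#'
#' @param observations data.frame from [read_ensemble_residues()].
#' @return The input with an added `norm_bfactor` column (`NA` where
#'   unresolved).
#' @export
normalized_bfactors <- function(observations) {
  stopifnot(all(c("structure_id", "resolved", "bfactor") %in%
                  names(observations)))
  observations$norm_bfactor <- NA_real_
  for (id in unique(observations$structure_id)) {
    i <- observations$structure_id == id & observations$resolved
    if (sum(i) < 2L)
      stop("structure '", id, "' has fewer than 2 resolved residues; ",
           "normalization needs spread", call. = FALSE)
    b <- observations$bfactor[i]
    s <- sqrt(mean((b - mean(b))^2))  # population SD: exact unit spread
    if (s == 0) {
      warning("structure '", id, "' has constant B-factors; ",
              "normalized values set to 0")
      observations$norm_bfactor[i] <- 0
    } else {
      observations$norm_bfactor[i] <- (b - mean(b)) / s
    }
  }
  observations
}

#' Presence and flexibility profile of a residue range
#'
#' For each residue number, the fraction of ensemble structures in which the
#' residue is resolved (a proxy for local order: flexible loop residues are
#' unsolved in many crystals) and the mean within-structure normalized
#' B-factor over the structures that do resolve it.
#'
#' @param observations data.frame from [read_ensemble_residues()], one chain
#'   per structure.
#' @return data.frame with columns `residue_number`, `presence_fraction`
#'   (0-1 scale), `mean_norm_bfactor` (`NA` for never-resolved residues) and
#'   `n_structures`.
#' @export
presence_profile <- function(observations) {
  stopifnot(all(c("structure_id", "residue_number", "resolved") %in%
                  names(observations)))
  if (nrow(observations) == 0L) stop("no observations supplied", call. = FALSE)
  if (is.null(observations$norm_bfactor))
    observations <- normalized_bfactors(observations)
  n_struct <- length(unique(observations$structure_id))
  res <- sort(unique(observations$residue_number))
  out <- do.call(rbind, lapply(res, function(r) {
    o <- observations[observations$residue_number == r, ]
    nb <- o$norm_bfactor[o$resolved]
    data.frame(
      residue_number = as.integer(r),
      presence_fraction = sum(o$resolved) / n_struct,
      mean_norm_bfactor = if (length(nb)) mean(nb) else NA_real_,
      n_structures = n_struct
    )
  }))
  rownames(out) <- NULL
  out
}
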