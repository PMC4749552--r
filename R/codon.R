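# Codon-level mutational accessibility: minimum nucleotide substitutions and
# codon-usage change for amino-acid substitutions.

#' Standard genetic code
#'
#' Returns the standard genetic code as a named character vector mapping the
#' 64 DNA codons to 1-letter amino acids (stop = `"*"`), taken from
#' [Biostrings::GENETIC_CODE]. Supply an alternative 64-entry mapping to the
#' accessibility functions to use a non-standard code.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  code
}

#' Human codon-usage table
#'
#' Relative synonymous codon usage for the human genome, expressed as the
#' fraction of synonymous usage (values for the codons of one amino acid sum
#' to 1, up to rounding of the published two-decimal fractions). Used to
#' score the change in codon usage caused by a missense mutation: mutating a
#' frequent codon to a rare one can lower translation efficiency.
#'
#' @return Named numeric vector over the 64 codons (stop codons included).
#' @export
codon_usage_human <- function() {
  c(
    TTT = 0.46, TTC = 0.54, TTA = 0.08, TTG = 0.13,
    CTT = 0.13, CTC = 0.20, CTA = 0.07, CTG = 0.40,
    ATT = 0.36, ATC = 0.47, ATA = 0.17, ATG = 1.00,
    GTT = 0.18, GTC = 0.24, GTA = 0.12, GTG = 0.46,
    TCT = 0.19, TCC = 0.22, TCA = 0.15, TCG = 0.05,
    AGT = 0.15, AGC = 0.24,
    CCT = 0.29, CCC = 0.32, CCA = 0.28, CCG = 0.11,
    ACT = 0.25, ACC = 0.36, ACA = 0.28, ACG = 0.11,
    GCT = 0.27, GCC = 0.40, GCA = 0.23, GCG = 0.11,
    TAT = 0.44, TAC = 0.56, TAA = 0.30, TAG = 0.24,
    CAT = 0.42, CAC = 0.58, CAA = 0.27, CAG = 0.73,
    AAT = 0.47, AAC = 0.53, AAA = 0.43, AAG = 0.57,
    GAT = 0.46, GAC = 0.54, GAA = 0.42, GAG = 0.58,
    TGT = 0.46, TGC = 0.54, TGA = 0.47, TGG = 1.00,
    CGT = 0.08, CGC = 0.18, CGA = 0.11, CGG = 0.20,
    AGA = 0.21, AGG = 0.21,
    GGT = 0.16, GGC = 0.34, GGA = 0.25, GGG = 0.25
  )
}

# Validate and canonicalize a codon string; errors carry the offending value.
check_codon <- function(codon, code) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon))
    stop("codon must be a single character string, got: ",
         deparse(codon), call. = FALSE)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("invalid codon '", codon, "': must be 3 bases over A/C/G/T",
         call. = FALSE)
  if (!codon %in% names(code))
    stop("codon '", codon, "' not in the supplied genetic code", call. = FALSE)
  if (code[[codon]] == "*")
    stop("codon '", codon, "' is a stop codon; only sense codons are valid",
         call. = FALSE)
  codon
}

check_target_aa <- function(target_aa) {
  if (!is.character(target_aa) || length(target_aa) != 1L || is.na(target_aa))
    stop("target_aa must be a single character", call. = FALSE)
  target_aa <- toupper(target_aa)
  if (target_aa == "*")
    stop("stop codons are not valid substitution targets (missense scope only)",
         call. = FALSE)
  if (!target_aa %in% AMINO_ACIDS)
    stop("unknown amino acid '", target_aa, "'", call. = FALSE)
  target_aa
}

hamming3 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Minimum nucleotide substitutions for an amino-acid change
#'
#' The smallest number of base changes turning `wt_codon` into any codon of
#' `target_aa` under the genetic code: the mutational-accessibility distance
#' of a missense change. V600E of BRAF (GTG to GAG) needs a single base
#' change, while V600K or V600D need two and V600H three — a difference the
#' cancer-frequency model treats as a predictor in its own right.
#'
#' @param wt_codon Wild-type codon (3 DNA bases; must be a sense codon).
#' @param target_aa Target amino acid, 1-letter code (stop not allowed).
#' @param code Genetic code as returned by [genetic_code()].
#' @return Integer in 0..3; 0 if and only if `target_aa` is the amino acid
#'   already encoded by `wt_codon`.
#' @export
#' @examples
#' min_nt_substitutions("GTG", "E")  # 1: the V600E route
#' min_nt_substitutions("GTG", "K")  # 2
#' min_nt_substitutions("GTG", "H")  # 3
min_nt_substitutions <- function(wt_codon, target_aa, code = genetic_code()) {
  wt_codon <- check_codon(wt_codon, code)
  target_aa <- check_target_aa(target_aa)
  target_codons <- names(code)[code == target_aa]
  min(vapply(target_codons, hamming3, integer(1), a = wt_codon))
}

#' Mutant codons at the minimal substitution distance
#'
#' All codons of `target_aa` whose Hamming distance to `wt_codon` equals
#' [min_nt_substitutions()]. These are the codons a minimal mutational path
#' can end in, and the candidate set for the codon-usage change.
#'
#' @inheritParams min_nt_substitutions
#' @return Character vector of codons (at least one).
#' @export
minimal_mutant_codons <- function(wt_codon, target_aa, code = genetic_code()) {
  wt_codon <- check_codon(wt_codon, code)
  target_aa <- check_target_aa(target_aa)
  target_codons <- names(code)[code == target_aa]
  d <- vapply(target_codons, hamming3, integer(1), a = wt_codon)
  sort(target_codons[d == min(d)])
}

#' Change in codon usage caused by a missense mutation
#'
#' Usage of the mutant codon minus usage of the wild-type codon. When several
#' mutant codons are reachable at the minimal substitution distance, the one
#' with maximal usage is taken (the most accessible high-expression outcome);
#' remaining ties break alphabetically so the result is deterministic.
#'
#' @inheritParams min_nt_substitutions
#' @param usage Codon-usage table, named numeric over at least all sense
#'   codons; default [codon_usage_human()] (fraction of synonymous usage).
#' @return List with `usage_delta` (mutant minus wild-type usage),
#'   `mutant_codon` (the selected codon) and `min_substitutions`.
#' @export
#' @examples
#' usage_delta("GTG", "E")  # GAG selected; 0.58 - 0.46
usage_delta <- function(wt_codon, target_aa, code = genetic_code(),
                        usage = codon_usage_human()) {
  wt_codon <- check_codon(wt_codon, code)
  target_aa <- check_target_aa(target_aa)
  cands <- minimal_mutant_codons(wt_codon, target_aa, code)
  missing <- setdiff(c(wt_codon, cands), names(usage))
  if (length(missing))
    stop("codon usage table lacks entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  u <- usage[cands]
  chosen <- cands[which.max(u)]  # which.max takes the first (alphabetical) tie
  list(
    usage_delta = unname(usage[[chosen]] - usage[[wt_codon]]),
    mutant_codon = chosen,
    min_substitutions = min_nt_substitutions(wt_codon, target_aa, code)
  )
}

#' Mutational-accessibility table for a set of positions
#'
#' Expands each reference position to all 20 amino-acid substitutions
#' (including the identity substitution, kept as a control) and records the
#' minimal nucleotide substitution distance, the minimal-distance mutant
#' codons, the selected mutant codon and the codon-usage change.
#'
#' @param reference data.frame with columns `position`, `wt_aa`, `codon`;
#'   default [braf_pocket_reference()].
#' @param code,usage See [usage_delta()].
#' @return data.frame with one row per position x amino acid: `position`,
#'   `wt_aa`, `mut_aa`, `wt_codon`, `min_substitutions`, `minimal_codons`
#'   (comma-separated), `mutant_codon`, `usage_delta`.
#' @export
accessibility_table <- function(reference = braf_pocket_reference(),
                                code = genetic_code(),
                                usage = codon_usage_human()) {
  stopifnot(all(c("position", "wt_aa", "codon") %in% names(reference)))
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    pos <- reference$position[i]
    wt_codon <- check_codon(reference$codon[i], code)
    wt_aa <- toupper(reference$wt_aa[i])
    if (code[[wt_codon]] != wt_aa)
      stop("reference codon ", wt_codon, " at position ", pos,
           " does not encode ", wt_aa, call. = FALSE)
    do.call(rbind, lapply(AMINO_ACIDS, function(aa) {
      ud <- usage_delta(wt_codon, aa, code, usage)
      data.frame(
        position = pos, wt_aa = wt_aa, mut_aa = aa, wt_codon = wt_codon,
        min_substitutions = ud$min_substitutions,
        minimal_codons = paste(minimal_mutant_codons(wt_codon, aa, code),
                               collapse = ","),
        mutant_codon = ud$mutant_codon,
        usage_delta = ud$usage_delta,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  out[order(out$position, out$mut_aa), , drop = FALSE]
}
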