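# Assembly of the seven-predictor feature matrix and the transformed
# cancer-frequency response, one row per mutation.

FEATURE_NAMES <- c(
  "f1_inactive_destab",   # destabilization of inactive conformation/folding
  "f2_active_destab",     # destabilization of active conformation (folding)
  "f3_loop_destab",       # destabilization of inactive loop (flexibility-corrected)
  "f4_nt_substitutions",  # minimum nucleotide substitutions
  "f5_usage_delta",       # change in codon usage frequency
  "f6_saltbridge",        # phosphomimetic salt-bridge energy
  "f7_solvh_delta"        # change in hydrophobic solvation energy
)

#' Transform a mutation count into the regression response
#'
#' Somatic mutation counts span four orders of magnitude (a handful of
#' occurrences up to the >20,000 of V600E), so the default response is
#' `log10(count + 1)`; `raw` and `binary` (seen at all or not) are available
#' alternatives. All modes are monotone in the count.
#'
#' @param count Non-negative integer vector of occurrence counts.
#' @param mode `"log10p1"` (default), `"raw"` or `"binary"`.
#' @return Numeric vector.
#' @export
#' @examples
#' transform_frequency(c(0, 9, 999))  # 0, 1, 3
transform_frequency <- function(count, mode = c("log10p1", "raw", "binary")) {
  mode <- match.arg(mode)
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  switch(mode,
         log10p1 = log10(count + 1),
         raw = as.numeric(count),
         binary = as.numeric(count > 0))
}

#' Assemble the feature matrix and response
#'
#' Inner-joins per-mutation energy summaries, codon accessibility records and
#' frequency counts on the mutation key (position, wild-type, mutant) and
#' lays out the seven predictors in their fixed order:
#' 1 inactive destabilization, 2 active destabilization, 3 corrected
#' inactive-loop destabilization, 4 minimum nucleotide substitutions,
#' 5 codon-usage change, 6 salt bridge, 7 hydrophobic solvation change.
#' Mutations missing from any input are dropped with a warning; zero-count
#' mutations are retained (they form the low-frequency stratum of the
#' balanced forest splits).
#'
#' @param summaries Output of [summarize_energies()].
#' @param accessibility Output of [accessibility_table()].
#' @param frequencies data.frame with columns `position`, `wt_aa`, `mut_aa`,
#'   `count`.
#' @param response_mode Passed to [transform_frequency()].
#' @return data.frame with `mutation`, `position`, `wt_aa`, `mut_aa`, the
#'   seven feature columns, `count` and `response`, ordered by position then
#'   mutant amino acid.
#' @export
build_feature_matrix <- function(summaries, accessibility, frequencies,
                                 response_mode = "log10p1") {
  key <- function(d) paste(d$position, d$wt_aa, d$mut_aa, sep = "_")
  ks <- key(summaries); ka <- key(accessibility); kf <- key(frequencies)
  shared <- intersect(intersect(ks, ka), kf)
  if (length(shared) == 0L)
    stop("no mutations shared by all three inputs", call. = FALSE)
  dropped <- setdiff(union(union(ks, ka), kf), shared)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " mutation(s) absent from at least one input: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")

  s <- summaries[match(shared, ks), ]
  a <- accessibility[match(shared, ka), ]
  f <- frequencies[match(shared, kf), ]

  out <- data.frame(
    mutation = mutation_id(s$wt_aa, s$position, s$mut_aa),
    position = s$position, wt_aa = s$wt_aa, mut_aa = s$mut_aa,
    f1_inactive_destab = s$mean_ddg_inactive,
    f2_active_destab = s$mean_ddg_active,
    f3_loop_destab = s$loop_energy_corrected,
    f4_nt_substitutions = a$min_substitutions,
    f5_usage_delta = a$usage_delta,
    f6_saltbridge = s$saltbridge,
    f7_solvh_delta = s$ddg_solvh_inactive,
    count = f$count,
    response = transform_frequency(f$count, response_mode),
    stringsAsFactors = FALSE
  )
  if (anyNA(out[, FEATURE_NAMES]))
    stop("assembled feature matrix contains missing values", call. = FALSE)
  out <- out[order(out$position, out$mut_aa), ]
  rownames(out) <- NULL
  out
}

#' Read a mutation-frequency table
#'
#' Tab-delimited with header columns `position`, `wt_aa`, `mut_aa`, `count`
#' (somatic occurrence counts per amino-acid substitution, catalogue-export
#' style).
#' @param path File path.
#' @return data.frame.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("position", "wt_aa", "mut_aa", "count")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("frequency table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(tab$count < 0)) stop("negative counts in frequency table",
                               call. = FALSE)
  tab
}

#' Write a feature matrix or frequency table
#' @param x data.frame.
#' @param path Output path (tab-delimited, header, no quoting).
#' @export
write_feature_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
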