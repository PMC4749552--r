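# Post-processing of per-mutation folding free-energy (ddG) tables computed
# on active- and inactive-state structure templates: threshold
# classification, state averaging, loop-presence (flexibility) weighting,
# phosphomimetic salt-bridge correction, and the composite activation score.

mutation_id <- function(wt_aa, position, mut_aa) {
  paste0(wt_aa, position, mut_aa)
}

#' Configuration of thresholds and corrections
#'
#' @param destabilization_threshold Strict lower bound (kcal/mol) above which
#'   a mean ddG is called destabilizing. The default 0.8 is twice the
#'   standard deviation of the empirical force-field energies.
#' @param loop_region Residue interval of the activation-segment loop
#'   (default Leu597-Gly615) over which the flexibility correction applies.
#' @param saltbridge_value Favorable energy (kcal/mol, must be <= 0) granted
#'   to phosphomimetic Asp/Glu substitutions at the phospho-positions; the
#'   study calibrated it from a phospho-Ser to Ser calculation on the
#'   cAMP-dependent protein kinase (PDB 1ATP) but never printed the number,
#'   so reproduction runs must set it explicitly. Default -2.0 kcal/mol is a
#'   placeholder of plausible phosphomimetic magnitude.
#' @param saltbridge_positions Residues whose Asp/Glu mutants can reach
#'   Arg575 (default Thr599, Lys601, Ser602). Position 600 never qualifies:
#'   its side chain points away from Arg575 in the active conformation.
#' @param saltbridge_residues Amino acids treated as phosphomimetic.
#' @param presence_correction Form of the loop flexibility correction;
#'   only `"multiplicative"` (energy x presence fraction) is implemented.
#' @return Object of class `energy_config` (a list).
#' @export
energy_config <- function(destabilization_threshold = 0.8,
                          loop_region = AS_LOOP_REGION,
                          saltbridge_value = -2.0,
                          saltbridge_positions = c(599L, 601L, 602L),
                          saltbridge_residues = c("D", "E"),
                          presence_correction = "multiplicative") {
  stopifnot(destabilization_threshold > 0, saltbridge_value <= 0)
  presence_correction <- match.arg(presence_correction, "multiplicative")
  structure(list(
    destabilization_threshold = destabilization_threshold,
    loop_region = as.integer(loop_region),
    saltbridge_value = saltbridge_value,
    saltbridge_positions = as.integer(saltbridge_positions),
    saltbridge_residues = saltbridge_residues,
    presence_correction = presence_correction
  ), class = "energy_config")
}

#' Read a per-mutation ddG table
#'
#' Reads a tab-delimited table of per-template folding energy changes
#' (mutant minus wild type, kcal/mol) in the style of force-field
#' mutational-scan output: one row per mutation per template structure.
#' Required columns: `template`, `position`, `wt_aa`, `mut_aa`, `ddg_total`,
#' `ddg_solvh` (hydrophobic/apolar solvation term). An optional `ddg_loop`
#' column carries the loop-restricted energy of the mutation; further
#' columns (e.g. the remaining term decomposition) are kept as-is.
#'
#' @param path File path of the tab-delimited table (with header).
#' @param template_states Named character vector mapping each template id to
#'   `"active"` or `"inactive"`.
#' @return data.frame of energy records with a `state` column added.
#' @export
read_ddg_table <- function(path, template_states) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("template", "position", "wt_aa", "mut_aa",
                "ddg_total", "ddg_solvh")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("ddG table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  assign_states(tab, template_states)
}

assign_states <- function(records, template_states) {
  if (is.null(names(template_states)) ||
      !all(template_states %in% c("active", "inactive")))
    stop("template_states must be a named vector of 'active'/'inactive'",
         call. = FALSE)
  unknown <- setdiff(unique(records$template), names(template_states))
  if (length(unknown))
    stop("template(s) not in the state map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  records$state <- unname(template_states[records$template])
  if (any(!is.finite(records$ddg_total)))
    stop("non-finite ddg_total values in table", call. = FALSE)
  records
}

#' Write a ddG table
#'
#' Tab-delimited, plain text, no quoting or row names; the on-disk
#' interchange format read back by [read_ddg_table()].
#' @param records data.frame of energy records.
#' @param path Output file path.
#' @export
write_ddg_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Enumerate the mutational scan space
#'
#' Every position x all 20 amino acids (identity substitutions included as
#' controls) x every template structure. The reference scan — 14 pocket
#' positions, 5 templates — yields 14 x 20 x 5 = 1400 structural models.
#'
#' @param reference data.frame with `position` and `wt_aa` columns
#'   (default [braf_pocket_reference()]).
#' @param templates Character vector of template structure ids.
#' @return data.frame with columns `template`, `position`, `wt_aa`,
#'   `mut_aa`; zero rows when `templates` is empty.
#' @export
enumerate_mutation_space <- function(reference = braf_pocket_reference(),
                                     templates) {
  stopifnot(nrow(reference) > 0)
  grid <- expand.grid(mut_aa = AMINO_ACIDS,
                      position = reference$position,
                      template = as.character(templates),
                      stringsAsFactors = FALSE)
  grid$wt_aa <- reference$wt_aa[match(grid$position, reference$position)]
  grid[, c("template", "position", "wt_aa", "mut_aa")]
}

#' Destabilization call for a mean ddG
#'
#' Strictly greater than the threshold (default 0.8 kcal/mol): a value at
#' exactly the threshold is not destabilizing.
#'
#' @param mean_ddg Numeric vector of mean ddG values (kcal/mol).
#' @param cfg [energy_config()].
#' @return Logical vector.
#' @export
classify_destabilizing <- function(mean_ddg, cfg = energy_config()) {
  stopifnot(all(is.finite(mean_ddg)))
  mean_ddg > cfg$destabilization_threshold
}

#' Mean ddG across templates of one state
#'
#' @param records Energy records (data.frame with `state`, `position`,
#'   `wt_aa`, `mut_aa`, and the averaged column).
#' @param position,wt_aa,mut_aa The mutation.
#' @param state `"active"` or `"inactive"`.
#' @param column Which energy column to average (default `ddg_total`).
#' @return Arithmetic mean (kcal/mol).
#' @export
state_average <- function(records, position, wt_aa, mut_aa, state,
                          column = "ddg_total") {
  i <- records$position == position & records$wt_aa == wt_aa &
    records$mut_aa == mut_aa & records$state == state
  if (!any(i))
    stop("no ", state, "-state records for ",
         mutation_id(wt_aa, position, mut_aa), call. = FALSE)
  mean(records[[column]][i])
}

#' Pairwise template correlations of mutational energies
#'
#' Pearson correlation between every pair of templates over their shared
#' mutations. Templates of the same conformational state correlate well;
#' active-vs-inactive pairs correlate poorly — the pattern that justifies
#' treating the two states separately.
#'
#' @param records Energy records with a `state` column.
#' @param column Energy column to correlate (default `ddg_total`).
#' @return Symmetric correlation matrix with unit diagonal and a `states`
#'   attribute (named vector template -> state).
#' @export
pairwise_state_correlation <- function(records, column = "ddg_total") {
  templates <- unique(records$template)
  if (length(templates) < 2L)
    stop("need at least 2 templates", call. = FALSE)
  key <- mutation_id(records$wt_aa, records$position, records$mut_aa)
  wide <- tapply(records[[column]], list(key, records$template), mean)
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3L)
    stop("fewer than 3 mutations shared by all templates", call. = FALSE)
  m <- stats::cor(wide)
  states <- records$state[match(colnames(m), records$template)]
  names(states) <- colnames(m)
  attr(m, "states") <- states
  m
}

#' Within- versus cross-state correlation summary
#'
#' @param corr Matrix from [pairwise_state_correlation()].
#' @return List with `mean_within`, `mean_cross` and `gap` (within minus
#'   cross), averaging the off-diagonal entries of each block.
#' @export
state_correlation_summary <- function(corr) {
  states <- attr(corr, "states")
  stopifnot(!is.null(states))
  same <- outer(states, states, "==")
  off <- !diag(nrow(corr))
  within <- mean(corr[same & off])
  cross <- mean(corr[!same])
  list(mean_within = within, mean_cross = cross, gap = within - cross)
}

#' Flexibility correction of loop energies
#'
#' Residues that are often unresolved in crystal structures are flexible, and
#' mutations there have less impact on unfolding than the rigid-pocket
#' energies suggest. For inactive-state energies at loop positions the energy
#' is therefore scaled by the fraction of ensemble structures resolving the
#' position; energies at non-loop positions, and all active-state energies,
#' pass through unchanged (the active templates resolve the loop only to
#' position 600 and show no destabilization there).
#'
#' @param loop_energy Energy to correct (kcal/mol).
#' @param position Residue position of the mutation.
#' @param profile [presence_profile()] output covering the loop region.
#' @param state `"active"` or `"inactive"`.
#' @param cfg [energy_config()].
#' @return Corrected energy (kcal/mol); magnitude never exceeds the input.
#' @export
loop_presence_correction <- function(loop_energy, position, profile,
                                     state = "inactive",
                                     cfg = energy_config()) {
  state <- match.arg(state, c("inactive", "active"))
  if (state == "active" || !(position %in% cfg$loop_region))
    return(loop_energy)
  i <- match(position, profile$residue_number)
  if (is.na(i))
    stop("presence profile has no entry for loop position ", position,
         call. = FALSE)
  loop_energy * profile$presence_fraction[i]
}

#' Phosphomimetic salt-bridge correction
#'
#' Asp/Glu substitutions at the activation-segment phospho-positions (Thr599,
#' Ser602) — and at Lys601, which can also reach Arg575 — mimic activating
#' phosphorylation by forming a salt bridge that stabilizes the active
#' conformation; they receive the configured favorable energy. Position 600
#' is excluded: its side chain always points away from Arg575.
#'
#' @param position,mut_aa The substitution.
#' @param cfg [energy_config()].
#' @return `cfg$saltbridge_value` (<= 0) or 0.
#' @export
saltbridge_correction <- function(position, mut_aa, cfg = energy_config()) {
  qualifies <- position %in% cfg$saltbridge_positions &
    mut_aa %in% cfg$saltbridge_residues & position != 600L
  ifelse(qualifies, cfg$saltbridge_value, 0)
}

#' Composite activation score of a mutation
#'
#' Corrected inactive-loop energy (release of the autoinhibited segment)
#' minus the active-state folding penalty (with the salt-bridge correction
#' stabilizing the active conformation) plus the hydrophobic solvation term:
#'
#' `score = loop_corrected - (mean_active + saltbridge) + solvh_inactive`
#'
#' High scores mark mutations that open the activation segment without
#' wrecking the active fold — the profile of activating driver mutations.
#'
#' @param loop_energy_corrected Flexibility-corrected inactive loop energy.
#' @param mean_ddg_active Mean ddG over active templates.
#' @param ddg_solvh_inactive Mean hydrophobic solvation term (inactive).
#' @param saltbridge Salt-bridge correction from [saltbridge_correction()].
#' @return Score in kcal/mol.
#' @export
activation_score <- function(loop_energy_corrected, mean_ddg_active,
                             ddg_solvh_inactive, saltbridge = 0) {
  stopifnot(all(is.finite(loop_energy_corrected)),
            all(is.finite(mean_ddg_active)),
            all(is.finite(ddg_solvh_inactive)))
  loop_energy_corrected - (mean_ddg_active + saltbridge) + ddg_solvh_inactive
}

#' Per-mutation energy summary
#'
#' Collapses per-template energy records into one row per mutation: state
#' means, the (corrected) inactive loop energy, the salt-bridge correction,
#' the solvation term, destabilization calls and the activation score.
#'
#' The loop energy is taken from the records' `ddg_loop` column when
#' present (a loop-restricted energy decomposition); otherwise it falls back
#' to the inactive `ddg_total` for mutations at loop positions and 0
#' elsewhere (a mutation outside the segment does not destabilize it).
#'
#' @param records Energy records with `state` assigned.
#' @param profile [presence_profile()] covering the loop region.
#' @param cfg [energy_config()].
#' @return data.frame, one row per mutation ordered by position then mutant
#'   amino acid, with columns `position`, `wt_aa`, `mut_aa`, `mutation`,
#'   `mean_ddg_inactive`, `mean_ddg_active`, `loop_energy`,
#'   `loop_energy_corrected`, `saltbridge`, `ddg_solvh_inactive`,
#'   `activation_score`, `destabilizing_inactive`, `destabilizing_active`.
#' @export
summarize_energies <- function(records, profile, cfg = energy_config()) {
  stopifnot(all(c("template", "state", "position", "wt_aa", "mut_aa",
                  "ddg_total", "ddg_solvh") %in% names(records)))
  muts <- unique(records[, c("position", "wt_aa", "mut_aa")])
  muts <- muts[order(muts$position, muts$mut_aa), , drop = FALSE]

  has_loop_col <- "ddg_loop" %in% names(records)
  rows <- lapply(seq_len(nrow(muts)), function(i) {
    pos <- muts$position[i]; wt <- muts$wt_aa[i]; mut <- muts$mut_aa[i]
    ri <- records$position == pos & records$wt_aa == wt & records$mut_aa == mut
    inact <- ri & records$state == "inactive"
    act <- ri & records$state == "active"
    if (!any(inact) || !any(act))
      stop("mutation ", mutation_id(wt, pos, mut),
           " lacks records in one of the states", call. = FALSE)
    mean_in <- mean(records$ddg_total[inact])
    mean_ac <- mean(records$ddg_total[act])
    loop <- if (has_loop_col) mean(records$ddg_loop[inact])
            else if (pos %in% cfg$loop_region) mean_in else 0
    loop_c <- loop_presence_correction(loop, pos, profile, "inactive", cfg)
    sb <- saltbridge_correction(pos, mut, cfg)
    solvh <- mean(records$ddg_solvh[inact])
    data.frame(
      position = pos, wt_aa = wt, mut_aa = mut,
      mutation = mutation_id(wt, pos, mut),
      mean_ddg_inactive = mean_in, mean_ddg_active = mean_ac,
      loop_energy = loop, loop_energy_corrected = loop_c,
      saltbridge = sb, ddg_solvh_inactive = solvh,
      activation_score = activation_score(loop_c, mean_ac, solvh, sb),
      destabilizing_inactive = classify_destabilizing(mean_in, cfg),
      destabilizing_active = classify_destabilizing(mean_ac, cfg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between a score and a phenotype
#'
#' Plain Pearson statistics for score-versus-measurement comparisons, e.g.
#' activation score against kinase activity, or folding energy against
#' protein solubility.
#'
#' @param scores,phenotype Paired numeric vectors (>= 3 complete pairs).
#' @return List with `r`, `r_squared` and `n`.
#' @export
correlate_with_phenotype <- function(scores, phenotype) {
  ok <- is.finite(scores) & is.finite(phenotype)
  if (sum(ok) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(scores[ok]) == 0 || stats::sd(phenotype[ok]) == 0)
    stop("undefined correlation: zero variance in input", call. = FALSE)
  r <- stats::cor(scores[ok], phenotype[ok])
  list(r = r, r_squared = r^2, n = sum(ok))
}
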