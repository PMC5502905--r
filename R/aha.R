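## Rule-based modified AHA plaque typing from quantitative T2 measures plus
## a calcium mask, and the confusion-table bookkeeping for agreement with
## histology-assigned types. The study population contains advanced lesions
## only, so the type set is IV-V (lipid core), VI (complicated /
## haemorrhagic), VII (calcified), VIII (fibrous).

.aha_levels <- c("IV_V", "VI", "VII", "VIII")

#' Modified AHA typing rules
#'
#' @param calcium_threshold Calcified-area \% above which a plaque is type
#'   VII (strict `>`).
#' @param min_core_pct Lipid-core \% at or above which a non-haemorrhagic,
#'   non-calcified plaque is type IV--V.
#' @return A list of class `aha_rules`.
#' @export
aha_rules <- function(calcium_threshold = 10, min_core_pct = 10) {
  check_number(calcium_threshold, "calcium_threshold", 0, 100)
  check_number(min_core_pct, "min_core_pct", 0, 100)
  structure(list(calcium_threshold = calcium_threshold,
                 min_core_pct = min_core_pct), class = "aha_rules")
}

#' Classify one plaque into a modified AHA type
#'
#' Deterministic precedence: type VI when significant haemorrhage is
#' present; otherwise VII when the calcified area exceeds the calcium
#' threshold; otherwise IV--V when the lipid core reaches the minimum core
#' size; otherwise VIII (fibrous).
#'
#' @param lipid_area_pct Plaque lipid-core area, \% of wall area.
#' @param significant_iph Logical: significant haemorrhage anywhere in the
#'   plaque.
#' @param calcium_area_pct Calcified area \% (from the calcium / TOF input
#'   mask, never inferred from T2).
#' @param rules An [aha_rules()].
#' @return A factor of length 1 with levels `IV_V`, `VI`, `VII`, `VIII`.
#' @export
classify_plaque_aha <- function(lipid_area_pct, significant_iph,
                                calcium_area_pct, rules = aha_rules()) {
  check_number(lipid_area_pct, "lipid_area_pct", 0, 100)
  check_number(calcium_area_pct, "calcium_area_pct", 0, 100)
  check_flag(significant_iph, "significant_iph")
  label <-
    if (significant_iph) "VI"
    else if (calcium_area_pct > rules$calcium_threshold) "VII"
    else if (lipid_area_pct >= rules$min_core_pct) "IV_V"
    else "VIII"
  factor(label, levels = .aha_levels)
}

#' Confusion table of predicted versus reference AHA types
#'
#' Rows are the reference (histology) types, columns the predicted (image)
#' types, in the fixed order IV_V, VI, VII, VIII; the table feeds
#' [cohens_kappa()].
#'
#' @param predicted,reference Vectors of AHA labels (factor or character).
#' @return A 4 x 4 integer matrix.
#' @export
agreement_table <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop2("'predicted' and 'reference' must have equal length")
  if (length(predicted) == 0L) stop2("empty inputs")
  p <- factor(as.character(predicted), levels = .aha_levels)
  r <- factor(as.character(reference), levels = .aha_levels)
  if (any(is.na(p)) || any(is.na(r)))
    stop2("labels must be among: ", paste(.aha_levels, collapse = ", "))
  tab <- table(reference = r, predicted = p)
  matrix(as.integer(tab), 4L, 4L, dimnames = dimnames(tab))
}
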