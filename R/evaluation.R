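#' Categorical map agreement: confusion matrix, overall accuracy, Cohen's kappa
#'
#' Cell-by-cell comparison of a predicted and an observed class map over an
#' optional mask. Overall accuracy is the percentage of correctly predicted
#' cells (`100 * trace / total`); Cohen's kappa corrects for chance agreement
#' computed from the marginal class proportions (unweighted).
#'
#' @param predicted,observed integer (or factor) matrices/vectors of class
#'   codes on the same grid and legend
#' @param mask optional logical matrix/vector selecting the cells to compare
#' @param levels class codes defining the legend; defaults to the codes
#'   present in either map
#' @return list of class `agreement_report`: `confusion` (classes x classes
#'   counts, predicted in rows), `overall_accuracy` (percent), `kappa`, `n`
#' @export
map_agreement <- function(predicted, observed, mask = NULL, levels = NULL) {
  p <- as.vector(predicted); o <- as.vector(observed)
  if (length(p) != length(o))
    stop("predicted and observed maps differ in size", call. = FALSE)
  if (!is.null(mask)) {
    m <- as.vector(mask)
    stopifnot(length(m) == length(p))
    p <- p[m]; o <- o[m]
  }
  if (length(p) == 0) stop("no cells to compare", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(c(p, o)))
  if (any(!(p %in% levels)) || any(!(o %in% levels)))
    stop("map codes outside the shared legend", call. = FALSE)
  cm <- table(factor(p, levels = levels), factor(o, levels = levels))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  structure(list(confusion = cm, overall_accuracy = 100 * po, kappa = kappa,
                 n = n),
            class = "agreement_report")
}

#' Hydrologic series skill: percent bias, NSE, RSR
#'
#' Standard model-skill scores for a modelled vs observed series:
#' `PBIAS = 100 * sum(obs - mod) / sum(obs)`,
#' `NSE = 1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2)`,
#' `RSR = RMSE / SD(obs)` with the population standard deviation, so that
#' `RSR = sqrt(1 - NSE)` exactly. NSE = 1 and RSR = 0 indicate a perfect
#' match; a model no better than the observed mean has NSE = 0 and RSR = 1.
#'
#' @param modelled,observed numeric vectors of equal length (>= 2)
#' @return list of class `skill_report`: `percent_bias`, `nse`, `rsr`
#' @export
series_skill <- function(modelled, observed) {
  if (length(modelled) != length(observed) || length(observed) < 2)
    stop("need two equal-length series with at least 2 points", call. = FALSE)
  if (anyNA(modelled) || anyNA(observed))
    stop("series contain missing values", call. = FALSE)
  ss_obs <- sum((observed - mean(observed))^2)
  if (ss_obs == 0)
    stop("observed series has zero variance: NSE/RSR undefined", call. = FALSE)
  err <- observed - modelled
  structure(list(percent_bias = 100 * sum(err) / sum(observed),
                 nse = 1 - sum(err^2) / ss_obs,
                 rsr = sqrt(sum(err^2) / ss_obs)),
            class = "skill_report")
}

#' Degraded wetland fraction
#'
#' Percentage of the wetland area that is terrestrially invaded non-woody
#' vegetation plus woody (River Red Gum) vegetation in poor condition.
#' Originally terrestrial area (terrestrial at t0, no remembered wetland
#' class) is excluded from the numerator, and from the denominator unless
#' `include_original_terrestrial = TRUE`.
#'
#' @param states patch-state data.frame (`class`, `memory`, `n_cells`) as
#'   produced by [run_coupled()]/[initial_patch_states()]
#' @param include_original_terrestrial count pre-existing dryland as part of
#'   the wetland extent (denominator only)
#' @return percent in `[0, 100]`
#' @export
degraded_fraction <- function(states, include_original_terrestrial = FALSE) {
  stopifnot(all(c("class", "memory", "n_cells") %in% names(states)))
  invaded <- states$class == CLS[["Terrestrial"]] & !is.na(states$memory)
  poor <- states$class == CLS[["RRG_poor"]]
  original <- states$class == CLS[["Terrestrial"]] & is.na(states$memory)
  denom <- if (include_original_terrestrial) sum(states$n_cells)
           else sum(states$n_cells[!original])
  if (denom == 0) return(0)
  100 * sum(states$n_cells[invaded | poor]) / denom
}

#' Longest continuous degradation spell
#'
#' Longest run of consecutive years whose degraded fraction is at or above
#' `level`.
#'
#' @param degraded_pct numeric vector of yearly degraded fractions (percent)
#' @param level threshold, percent
#' @return integer run length (0 if never reached)
#' @export
degradation_duration <- function(degraded_pct, level) {
  if (length(degraded_pct) == 0) stop("need at least one year", call. = FALSE)
  r <- rle(degraded_pct >= level)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}
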