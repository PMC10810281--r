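#' Conjugation efficiency
#'
#' The efficiency of plasmid conjugation is the ratio of transconjugant to
#' total recipient colony-forming units.
#'
#' @param transconjugants Transconjugant CFU count (>= 0).
#' @param recipients Recipient CFU count (> 0).
#' @return A list with `efficiency` and `below_detection` (`TRUE` when no
#'   transconjugants were observed, in which case the efficiency is 0 and
#'   downstream fold-interference is reported as a bound).
#' @export
conjugation_efficiency <- function(transconjugants, recipients) {
  stopifnot(length(transconjugants) == 1L, length(recipients) == 1L,
            transconjugants >= 0, recipients >= 0)
  if (recipients == 0)
    stop("recipients must be > 0 for a defined efficiency")
  list(efficiency = transconjugants / recipients,
       below_detection = transconjugants == 0)
}

#' Fold-interference between an untargeted and a targeted condition
#'
#' CRISPR interference strength is the ratio of conjugation efficiencies,
#' untargeted over targeted. When the targeted condition yielded zero
#' transconjugants, a detection floor of one transconjugant is substituted
#' and the result is flagged as a lower bound, reported in ">N-fold" style.
#'
#' @param untargeted,targeted Lists from [conjugation_efficiency()], or
#'   numeric efficiencies (in which case no bound logic applies unless the
#'   targeted recipients are supplied via `targeted_recipients`).
#' @param targeted_recipients Recipient count of the targeted condition,
#'   needed for the detection floor when a raw zero efficiency is passed.
#'
#' @return A list with `fold` (the fold-interference, using the detection
#'   floor when applicable), `is_lower_bound`, and `label` (e.g. `"12000-fold"`
#'   or `">10000-fold"`).
#' @export
fold_interference <- function(untargeted, targeted,
                              targeted_recipients = NULL) {
  as_eff <- function(x) {
    if (is.list(x)) x
    else list(efficiency = x, below_detection = x == 0)
  }
  u <- as_eff(untargeted)
  t <- as_eff(targeted)
  if (u$efficiency <= 0)
    stop("untargeted efficiency must be positive")
  if (t$below_detection) {
    if (is.list(targeted) && !is.null(targeted$recipients)) {
      floor_eff <- 1 / targeted$recipients
    } else if (!is.null(targeted_recipients)) {
      floor_eff <- 1 / targeted_recipients
    } else {
      stop("zero targeted efficiency needs the recipient count for the ",
           "1-transconjugant detection floor")
    }
    fold <- u$efficiency / floor_eff
    list(fold = fold, is_lower_bound = TRUE,
         label = sprintf(">%s-fold", format(fold, big.mark = " ",
                                            scientific = FALSE)))
  } else {
    fold <- u$efficiency / t$efficiency
    list(fold = fold, is_lower_bound = FALSE,
         label = sprintf("%s-fold", format(fold, big.mark = " ",
                                           scientific = FALSE)))
  }
}

#' Tenfold plaque dilution series
#'
#' A spot-titre series: strictly 10x increasing dilution factors, the
#' plaque count at each spot, and whether the spot showed confluent lawn
#' clearing (lysis without countable plaques).
#'
#' @param dilution_factor Strictly increasing powers of ten (e.g.
#'   `c(1, 10, 100, ...)`), the inverse of the dilution spotted.
#' @param plaques Non-negative integer plaque count per spot.
#' @param clearing Logical per spot: confluent clearing without countable
#'   plaques.
#' @return A data frame of class `plaque_series`.
#' @export
plaque_series <- function(dilution_factor, plaques, clearing) {
  stopifnot(length(dilution_factor) >= 1L,
            length(plaques) == length(dilution_factor),
            length(clearing) == length(dilution_factor),
            all(plaques >= 0))
  if (length(dilution_factor) > 1L &&
      any(abs(diff(log10(dilution_factor)) - 1) > 1e-9))
    stop("dilution factors must increase strictly by 10x")
  df <- data.frame(dilution_factor = dilution_factor,
                   plaques = as.integer(plaques),
                   clearing = as.logical(clearing))
  class(df) <- c("plaque_series", "data.frame")
  df
}

#' Plaque-forming units of a dilution series
#'
#' PFU is the plaque count at the most dilute spot with countable plaques,
#' multiplied by its dilution factor. When no spot has countable plaques
#' but lawn clearing is present, the substitution rule applies: one plaque
#' is recorded at the first dilution without clearing. With neither plaques
#' nor clearing anywhere, PFU is 0 and the series is below detection.
#'
#' @param series A [plaque_series()].
#' @return A list with `pfu`, `below_detection`, and `substituted` (`TRUE`
#'   when the one-plaque substitution rule was applied).
#' @export
series_pfu <- function(series) {
  stopifnot(inherits(series, "plaque_series"))
  countable <- which(series$plaques > 0L)
  if (length(countable) > 0L) {
    i <- max(countable)
    return(list(pfu = series$plaques[i] * series$dilution_factor[i],
                below_detection = FALSE, substituted = FALSE))
  }
  if (any(series$clearing)) {
    i <- which(!series$clearing)
    if (length(i) == 0L)
      # clearing through the whole series: one plaque one dilution further
      return(list(pfu = 1 * series$dilution_factor[nrow(series)] * 10,
                  below_detection = FALSE, substituted = TRUE))
    return(list(pfu = 1 * series$dilution_factor[min(i)],
                below_detection = FALSE, substituted = TRUE))
  }
  list(pfu = 0, below_detection = TRUE, substituted = FALSE)
}

#' Efficiency of plating (EOP)
#'
#' PFU of the test series divided by PFU of the control (non-targeting)
#' series, each computed by [series_pfu()] including the one-plaque
#' substitution rule for clearing-only series.
#'
#' @param test,control [plaque_series()] objects (or precomputed
#'   [series_pfu()] lists).
#' @return A list with `eop`, `pfu_test`, `pfu_control`,
#'   `below_detection` (test PFU was 0) and `substituted` (either series
#'   used the substitution rule).
#' @export
efficiency_of_plating <- function(test, control) {
  pt <- if (inherits(test, "plaque_series")) series_pfu(test) else test
  pc <- if (inherits(control, "plaque_series")) series_pfu(control)
        else control
  if (pc$pfu <= 0)
    stop("control PFU must be positive")
  list(eop = pt$pfu / pc$pfu,
       pfu_test = pt$pfu, pfu_control = pc$pfu,
       below_detection = isTRUE(pt$below_detection),
       substituted = isTRUE(pt$substituted) || isTRUE(pc$substituted))
}
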