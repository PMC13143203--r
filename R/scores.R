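#' Two-bottle preference score
#'
#' Percentage of total fluid intake taken from the tastant bottle over
#' the 48 h test window (bottle sides are swapped at 24 h upstream of
#' this calculation; volumes here are the summed totals):
#' `100 * tastant / (tastant + water)`. 50 is the no-preference line.
#'
#' @param tastant_ml,water_ml non-negative consumed volumes in ml.
#' @return preference in `[0, 100]`.
#' @export
two_bottle_preference <- function(tastant_ml, water_ml) {
  if (!is.numeric(tastant_ml) || !is.numeric(water_ml) ||
      length(tastant_ml) != 1L || length(water_ml) != 1L ||
      !is.finite(tastant_ml) || !is.finite(water_ml) ||
      tastant_ml < 0 || water_ml < 0)
    stop("volumes must be single non-negative numbers")
  total <- tastant_ml + water_ml
  if (total == 0) stop("total consumption is zero; score undefined")
  100 * tastant_ml / total
}

check_session <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("day", "block", "bottle", "licks") %in% names(trials)))
  if (nrow(trials) == 0L) stop("session has no trials")
  if (any(trials$block < 1L)) stop("block indices must be >= 1")
  if (any(trials$licks < 0) || any(trials$licks != round(trials$licks)))
    stop("lick counts must be non-negative integers")
  invisible(TRUE)
}

#' Brief-access lick ratio
#'
#' Mean licks across eligible tastant trials at one concentration,
#' pooled over the (typically two) testing days, divided by the mean
#' licks across eligible water trials. With `exclude_first_block = TRUE`
#' (the convention for the sweet panel, where first-block licking is
#' driven by thirst) block 1 of each day is dropped before averaging.
#' `per_day = TRUE` instead computes the ratio within each day and
#' averages the two ratios; the pooled form is the default.
#'
#' @param trials data frame of trials with columns `day`, `block`
#'   (1-based), `bottle` (`"water"` or a concentration label) and
#'   `licks`.
#' @param concentration the tastant bottle label to score.
#' @param exclude_first_block drop block 1 of every day.
#' @param per_day average per-day ratios instead of pooling trials.
#' @return non-negative lick ratio.
#' @export
lick_ratio <- function(trials, concentration, exclude_first_block = FALSE,
                       per_day = FALSE) {
  check_session(trials)
  if (exclude_first_block) trials <- trials[trials$block > 1L, , drop = FALSE]
  one_ratio <- function(tr) {
    w <- tr$licks[tr$bottle == "water"]
    t <- tr$licks[tr$bottle == concentration]
    if (length(w) == 0L || length(t) == 0L)
      stop("no eligible water or tastant trials after exclusion")
    if (mean(w) == 0) stop("mean water licks is zero; ratio undefined")
    mean(t) / mean(w)
  }
  if (!per_day) return(one_ratio(trials))
  mean(vapply(split(trials, trials$day), one_ratio, numeric(1)))
}

#' First-block thirst metric
#'
#' Total licks across the five first-block presentations of each testing
#' day, averaged across the days — a motivational-state control reported
#' alongside the lick ratio.
#'
#' @param trials data frame as in [lick_ratio()], covering the testing
#'   days to average.
#' @return mean first-block total licks.
#' @export
thirst_metric <- function(trials) {
  check_session(trials)
  days <- split(trials, trials$day)
  totals <- vapply(days, function(tr) {
    fb <- tr$licks[tr$block == 1L]
    if (length(fb) == 0L)
      stop("a testing day is missing its first block")
    sum(fb)
  }, numeric(1))
  mean(totals)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(target) - Ct(housekeeping)`; then
#' `ddCt = dCt - mean(dCt of the control group)` and the fold change is
#' `2^(-ddCt)`. Control centering uses the arithmetic mean of control
#' dCt values, so the geometric mean of the control-group folds is
#' exactly 1.
#'
#' @param ct_table data frame with columns `sample_id`, `group`, `gene`,
#'   `ct` (one Ct per sample and gene; collapse replicate wells first).
#' @param target_gene gene to quantify.
#' @param control_group value of `group` forming the reference set.
#' @param housekeeping reference gene name (default `"Rpl19"`).
#' @return data frame: `sample_id`, `group`, `dct`, `ddct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(ct_table, target_gene,
                             control_group = "control",
                             housekeeping = "Rpl19") {
  stopifnot(is.data.frame(ct_table),
            all(c("sample_id", "group", "gene", "ct") %in% names(ct_table)))
  if (any(!is.finite(ct_table$ct))) stop("all Ct values must be finite")
  tgt <- ct_table[ct_table$gene == target_gene, ]
  hk <- ct_table[ct_table$gene == housekeeping, ]
  if (nrow(tgt) == 0L) stop("no Ct rows for target gene '", target_gene, "'")
  i <- match(tgt$sample_id, hk$sample_id)
  if (any(is.na(i)))
    stop("missing housekeeping (", housekeeping, ") Ct for sample(s): ",
         paste(tgt$sample_id[is.na(i)], collapse = ", "))
  dct <- tgt$ct - hk$ct[i]
  ctrl <- tgt$group == control_group
  if (!any(ctrl)) stop("control group '", control_group, "' is empty")
  ddct <- dct - mean(dct[ctrl])
  data.frame(sample_id = tgt$sample_id, group = tgt$group, dct = dct,
             ddct = ddct, fold_change = 2^(-ddct),
             stringsAsFactors = FALSE)
}
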