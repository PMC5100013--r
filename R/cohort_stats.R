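# Cohort statistics: growth traits compared across time points on a paired
# panel of roots (repeated-measures ANOVA, then paired t-tests).

#' Paired panel of growth traits
#'
#' Validates a long-format panel: one row per root x time point, every root
#' present at every time point exactly once (the paired structure the tests
#' rely on).
#'
#' @param data Data frame with columns `root_id`, `time_label`, and one or
#'   more numeric trait columns.
#' @param time_levels Order of the time labels; default the order of first
#'   appearance.
#' @return `data` with class `trait_panel` and `time_label` as an ordered
#'   factor.
#' @export
trait_panel <- function(data, time_levels = NULL) {
  stopifnot(is.data.frame(data),
            all(c("root_id", "time_label") %in% names(data)))
  if (is.null(time_levels)) time_levels <- unique(data$time_label)
  data$time_label <- factor(data$time_label, levels = time_levels)
  tab <- table(data$root_id, data$time_label)
  if (any(tab != 1L)) {
    stop("pairing error: every root must appear exactly once at every time point",
         call. = FALSE)
  }
  structure(data, class = c("trait_panel", "data.frame"))
}

#' Repeated-measures one-way ANOVA on a trait
#'
#' Tests the effect of time point on the named trait across the paired panel
#' of roots, honouring the pairing by removing between-root variation (the
#' within-subjects error term; no sphericity correction is applied). With all
#' values identical the degenerate 0/0 statistic is reported as F = 0, p = 1.
#'
#' @param panel A [trait_panel()].
#' @param trait Name of the trait column.
#' @return List with `F`, `p_value`, `df` (numerator, denominator).
#' @export
trait_anova <- function(panel, trait) {
  stopifnot(inherits(panel, "trait_panel"), trait %in% names(panel))
  y <- panel[[trait]]
  time_f <- panel$time_label
  root_f <- factor(panel$root_id)
  if (nlevels(root_f) < 3L) stop("need >= 3 roots", call. = FALSE)
  fit <- stats::aov(y ~ time_f + root_f)
  tab <- summary(fit)[[1]]
  ss_time <- tab["time_f", "Sum Sq"]
  scale <- mean(y^2) + 1
  if (ss_time < 1e-12 * scale) {
    return(list(F = 0, p_value = 1,
                df = c(nlevels(time_f) - 1L,
                       (nlevels(time_f) - 1L) * (nlevels(root_f) - 1L))))
  }
  list(F = tab["time_f", "F value"],
       p_value = tab["time_f", "Pr(>F)"],
       df = c(tab["time_f", "Df"], tab["Residuals", "Df"]))
}

star_code <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Paired t-tests between time points
#'
#' Two-sided paired t-tests of the named trait for each contrast, with the
#' conventional star codes (*** p < 0.001, ** p < 0.01, * p < 0.05, ns
#' otherwise) and no multiplicity correction. Degenerate cases are flagged
#' explicitly rather than erroring: zero within-pair variance with zero mean
#' difference gives `p = NA` (flag `zero_variance`); identical non-zero
#' differences give an infinite t (flag `infinite_t`, star `***`).
#'
#' @param panel A [trait_panel()].
#' @param trait Name of the trait column.
#' @param contrasts List of length-2 character vectors of time labels;
#'   default: first level versus each later level.
#' @return Data frame with `contrast`, `t`, `df`, `p_value`, `star`, `flag`.
#' @export
paired_ttests <- function(panel, trait, contrasts = NULL) {
  stopifnot(inherits(panel, "trait_panel"), trait %in% names(panel))
  lv <- levels(panel$time_label)
  if (is.null(contrasts)) {
    contrasts <- lapply(lv[-1], function(b) c(lv[1], b))
  }
  rows <- lapply(contrasts, function(ct) {
    a <- panel[panel$time_label == ct[1], ]
    b <- panel[panel$time_label == ct[2], ]
    b <- b[match(a$root_id, b$root_id), ]
    d <- a[[trait]] - b[[trait]]
    n <- length(d)
    lab <- paste(ct[1], "vs", ct[2])
    if (stats::sd(d) < 1e-12 * (mean(abs(d)) + 1)) {
      if (mean(abs(d)) < 1e-12) {
        return(data.frame(contrast = lab, t = NA_real_, df = n - 1L,
                          p_value = NA_real_, star = NA_character_,
                          flag = "zero_variance", stringsAsFactors = FALSE))
      }
      return(data.frame(contrast = lab, t = sign(mean(d)) * Inf, df = n - 1L,
                        p_value = 0, star = "***",
                        flag = "infinite_t", stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a[[trait]], b[[trait]], paired = TRUE)
    data.frame(contrast = lab, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               star = star_code(tt$p.value), flag = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
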