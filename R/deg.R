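# Differential-expression classification on FPKM tables: expressed calls,
# a fold-change + Welch-t + FDR engine, zone-preference and stress-response
# classification, and Table-style set counts.
#
# The engine is a deliberately simple, transparent stand-in for count-based
# DE models: the package's inputs are FPKM tables, not reads, so per-gene
# two-sided unequal-variance t-tests on log2(FPKM + pseudocount) with
# Benjamini-Hochberg correction within each comparison are used. It is
# documented as such and validated on simulated tables with planted truth.

#' Call genes expressed or not expressed
#'
#' A gene is called expressed when its mean FPKM reaches `min_fpkm` in at
#' least `min_units` of the eight sampling units (zone x treatment x time).
#' Non-expressed genes receive status `"NOTEST"` in every comparison.
#'
#' @param table An `expression_table`.
#' @param min_fpkm Mean-FPKM threshold per unit; default 1.
#' @param min_units Minimum number of units reaching the threshold; default 1.
#' @return Named logical vector, one element per gene.
#' @export
call_expressed <- function(table, min_fpkm = 1, min_units = 1) {
  stopifnot(inherits(table, "expression_table"))
  units <- unique(table$design$unit)
  means <- vapply(units, function(u) {
    rowMeans(table$fpkm[, table$design$unit == u, drop = FALSE])
  }, numeric(nrow(table$fpkm)))
  rowSums(means >= min_fpkm) >= min_units
}

#' The eight canonical pairwise comparisons
#'
#' Four zone comparisons (EZ versus DZ, numerator EZ, within each treatment x
#' time) and four stress comparisons (PEG versus CTL, numerator PEG, within
#' each zone x time).
#'
#' @return Data frame with columns `name`, `numerator`, `denominator`,
#'   `family` (`"zone"` or `"stress"`), `zone`, `treatment`, `time`.
#' @export
default_comparisons <- function() {
  tt <- c("0.5h", "3h")
  zone <- data.frame(
    name = paste0("EZvsDZ_", rep(c("CTL", "PEG"), each = 2), "_", tt),
    numerator = paste0("EZ_", rep(c("CTL", "PEG"), each = 2), "_", tt),
    denominator = paste0("DZ_", rep(c("CTL", "PEG"), each = 2), "_", tt),
    family = "zone", zone = NA_character_,
    treatment = rep(c("CTL", "PEG"), each = 2), time = tt,
    stringsAsFactors = FALSE)
  stress <- data.frame(
    name = paste0("PEGvsCTL_", rep(c("DZ", "EZ"), each = 2), "_", tt),
    numerator = paste0(rep(c("DZ", "EZ"), each = 2), "_PEG_", tt),
    denominator = paste0(rep(c("DZ", "EZ"), each = 2), "_CTL_", tt),
    family = "stress", zone = rep(c("DZ", "EZ"), each = 2),
    treatment = NA_character_, time = tt,
    stringsAsFactors = FALSE)
  rbind(zone, stress)
}

#' Differential expression for one pairwise comparison
#'
#' For every gene: `log2fc = log2((mean FPKM_num + pseudocount) / (mean
#' FPKM_den + pseudocount))`; a two-sided unequal-variance (Welch) t-test on
#' the per-replicate `log2(FPKM + pseudocount)` values (with a variance floor
#' of 1e-6 on the log2 scale to avoid zero-variance singularities — two
#' identical, constant sides yield p = 1); and Benjamini-Hochberg q-values
#' computed within the comparison over the expressed (tested) genes only.
#' A gene is flagged `is_deg` when its status is OK, p < `alpha`,
#' q < `alpha`, and `|log2fc| >= fc_threshold`.
#'
#' @param table An `expression_table`.
#' @param numerator,denominator Sampling-unit labels (e.g. `"EZ_CTL_0.5h"`),
#'   or `comparison` may name a row of [default_comparisons()].
#' @param comparison Optional comparison name from [default_comparisons()].
#' @param pseudocount Added to FPKM before log2; default 1.
#' @param alpha Significance level for both p and q; default 0.05.
#' @param fc_threshold Absolute log2 fold-change gate; default 2.
#' @param expressed Logical vector from [call_expressed()]; computed with
#'   defaults when missing.
#' @return Data frame of class `deg_records`: `gene_id`, `comparison`,
#'   `log2fc`, `p_value`, `q_value`, `status` (`"OK"`/`"NOTEST"`), `is_deg`.
#' @export
differential_expression <- function(table, numerator = NULL, denominator = NULL,
                                    comparison = NULL, pseudocount = 1,
                                    alpha = 0.05, fc_threshold = 2,
                                    expressed = NULL) {
  stopifnot(inherits(table, "expression_table"))
  stopifnot_scalar(pseudocount, "pseudocount", nonneg = TRUE)
  if (!is.null(comparison)) {
    cmp <- default_comparisons()
    row <- cmp[cmp$name == comparison, ]
    if (nrow(row) != 1L) stop(sprintf("unknown comparison '%s'", comparison), call. = FALSE)
    numerator <- row$numerator; denominator <- row$denominator
    cmp_name <- comparison
  } else {
    cmp_name <- paste0(numerator, "_vs_", denominator)
  }
  if (identical(numerator, denominator)) {
    stop("numerator and denominator units must differ", call. = FALSE)
  }
  units <- table$design$unit
  ncols <- which(units == numerator)
  dcols <- which(units == denominator)
  if (!length(ncols) || !length(dcols)) {
    stop("comparison units not present in the table", call. = FALSE)
  }
  if (length(ncols) < 2L || length(dcols) < 2L) {
    stop("need >= 2 replicates per side", call. = FALSE)
  }
  if (is.null(expressed)) expressed <- call_expressed(table)

  f <- table$fpkm
  mn <- rowMeans(f[, ncols, drop = FALSE])
  md <- rowMeans(f[, dcols, drop = FALSE])
  log2fc <- log2((mn + pseudocount) / (md + pseudocount))

  ln <- log2(f[, ncols, drop = FALSE] + pseudocount)
  ld <- log2(f[, dcols, drop = FALSE] + pseudocount)
  n1 <- length(ncols); n2 <- length(dcols)
  m1 <- rowMeans(ln); m2 <- rowMeans(ld)
  v1 <- pmax(rowSums((ln - m1)^2) / (n1 - 1), 1e-6)
  v2 <- pmax(rowSums((ld - m2)^2) / (n2 - 1), 1e-6)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)

  q <- rep(NA_real_, length(p))
  q[expressed] <- stats::p.adjust(p[expressed], method = "BH")
  status <- ifelse(expressed, "OK", "NOTEST")
  p[!expressed] <- NA_real_
  is_deg <- !is.na(p) & p < alpha & !is.na(q) & q < alpha &
    abs(log2fc) >= fc_threshold
  structure(data.frame(gene_id = rownames(f), comparison = cmp_name,
                       log2fc = log2fc, p_value = p, q_value = q,
                       status = status, is_deg = is_deg,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("deg_records", "data.frame"))
}

records_matrix <- function(records_list, field) {
  stopifnot(length(records_list) >= 1L)
  genes <- records_list[[1]]$gene_id
  out <- vapply(records_list, function(r) {
    stopifnot(identical(r$gene_id, genes))
    r[[field]]
  }, vector(mode = if (field == "is_deg") "logical" else "numeric",
            length(genes)))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(genes))
  rownames(out) <- genes
  out
}

#' Classify zone-preferred expression
#'
#' From the four EZ-versus-DZ comparison record sets (EZ as numerator): a
#' gene is DZ-preferred under all four conditions when it is a DEG with
#' `log2fc < 0` in every comparison (EZ-preferred symmetrically with
#' `log2fc > 0`); the at-least-one-condition classes use "any" instead of
#' "all". The core-set flag duplicates the all-four definition (at least
#' 4-fold higher in one zone regardless of growth conditions, given the
#' default `|log2fc| >= 2` gate).
#'
#' @param records List of four `deg_records` for the EZ-vs-DZ comparisons.
#' @return Data frame with per-gene logical columns `dz_all4`, `ez_all4`,
#'   `dz_any`, `ez_any`, `any_condition`, `core_dz`, `core_ez`, and a
#'   `zone_class` factor.
#' @export
classify_zone_preference <- function(records) {
  if (length(records) != 4L) {
    stop("need the four EZ-vs-DZ comparison record sets", call. = FALSE)
  }
  deg <- records_matrix(records, "is_deg")
  fc <- records_matrix(records, "log2fc")
  dz_all4 <- rowSums(deg & fc < 0) == 4L
  ez_all4 <- rowSums(deg & fc > 0) == 4L
  dz_any <- rowSums(deg & fc < 0) >= 1L
  ez_any <- rowSums(deg & fc > 0) >= 1L
  any_condition <- rowSums(deg) >= 1L
  zone_class <- factor(ifelse(dz_all4, "DZ-preferred",
                       ifelse(ez_all4, "EZ-preferred",
                       ifelse(any_condition, "some-conditions", "none"))),
                       levels = c("DZ-preferred", "EZ-preferred",
                                  "some-conditions", "none"))
  data.frame(gene_id = rownames(deg), dz_all4 = dz_all4, ez_all4 = ez_all4,
             dz_any = dz_any, ez_any = ez_any, any_condition = any_condition,
             core_dz = dz_all4, core_ez = ez_all4, zone_class = zone_class,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify the osmotic-stress response
#'
#' From the four PEG-versus-CTL comparison record sets (one per zone x time):
#' a gene is stress-responsive when it is a DEG in at least one of them. Per
#' zone, the timing class is `early-only` (DEG at 0.5 h only), `sustained`
#' (DEG at both times with the same sign), or `late` (3 h only); opposite
#' signs at the two times are labelled `mixed`. A global timing class across
#' zones is reported the same way.
#'
#' @param records Named list of four `deg_records`; names must identify zone
#'   and time as in [default_comparisons()] (`PEGvsCTL_<zone>_<time>`).
#' @return Data frame with `responsive`, per-zone timing and direction, and
#'   `timing_global`.
#' @export
classify_stress_response <- function(records) {
  need <- paste0("PEGvsCTL_", rep(c("DZ", "EZ"), each = 2), "_", c("0.5h", "3h"))
  if (!all(need %in% names(records))) {
    stop("records must be named with the four PEGvsCTL_<zone>_<time> comparisons",
         call. = FALSE)
  }
  deg <- records_matrix(records[need], "is_deg")
  fc <- records_matrix(records[need], "log2fc")
  colnames(deg) <- colnames(fc) <- need

  timing_for <- function(early, late, fce, fcl) {
    ifelse(early & late, ifelse(sign(fce) == sign(fcl), "sustained", "mixed"),
    ifelse(early, "early-only", ifelse(late, "late", NA_character_)))
  }
  dz_timing <- timing_for(deg[, "PEGvsCTL_DZ_0.5h"], deg[, "PEGvsCTL_DZ_3h"],
                          fc[, "PEGvsCTL_DZ_0.5h"], fc[, "PEGvsCTL_DZ_3h"])
  ez_timing <- timing_for(deg[, "PEGvsCTL_EZ_0.5h"], deg[, "PEGvsCTL_EZ_3h"],
                          fc[, "PEGvsCTL_EZ_0.5h"], fc[, "PEGvsCTL_EZ_3h"])
  early_any <- deg[, "PEGvsCTL_DZ_0.5h"] | deg[, "PEGvsCTL_EZ_0.5h"]
  late_any <- deg[, "PEGvsCTL_DZ_3h"] | deg[, "PEGvsCTL_EZ_3h"]
  timing_global <- ifelse(early_any & late_any, "sustained",
                   ifelse(early_any, "early-only",
                   ifelse(late_any, "late", NA_character_)))
  dir_of <- function(zone) {
    f <- fc[, paste0("PEGvsCTL_", zone, "_", c("0.5h", "3h")), drop = FALSE]
    d <- deg[, paste0("PEGvsCTL_", zone, "_", c("0.5h", "3h")), drop = FALSE]
    s <- rowSums(sign(f) * d)
    ifelse(rowSums(d) == 0, NA_character_,
           ifelse(s > 0, "up", ifelse(s < 0, "down", "mixed")))
  }
  data.frame(gene_id = rownames(deg),
             responsive = rowSums(deg) >= 1L,
             dz_responsive = deg[, "PEGvsCTL_DZ_0.5h"] | deg[, "PEGvsCTL_DZ_3h"],
             ez_responsive = deg[, "PEGvsCTL_EZ_0.5h"] | deg[, "PEGvsCTL_EZ_3h"],
             dz_timing = dz_timing, ez_timing = ez_timing,
             dz_direction = dir_of("DZ"), ez_direction = dir_of("EZ"),
             timing_global = timing_global,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize DEG set counts
#'
#' Builds the set counts of the zone-preference and stress-response
#' classifications and enforces the partition invariants: DZ-preferred +
#' EZ-preferred = zone DEGs under all four conditions; core sets are subsets
#' of the preferred sets; the all-four set is a subset of the at-least-one
#' set. Any violation raises an internal-consistency error rather than being
#' reported silently.
#'
#' @param zone Result of [classify_zone_preference()].
#' @param stress Result of [classify_stress_response()].
#' @param stress_records The four PEG-vs-CTL `deg_records` (named), used for
#'   the per-zone, per-time up/down splits.
#' @return List of class `deg_summary` with named counts.
#' @export
summarize_counts <- function(zone, stress, stress_records = NULL) {
  all4 <- sum(zone$dz_all4) + sum(zone$ez_all4)
  if (any(zone$dz_all4 & zone$ez_all4)) {
    stop("internal consistency: a gene is both DZ- and EZ-preferred", call. = FALSE)
  }
  if (any((zone$dz_all4 | zone$ez_all4) & !zone$any_condition)) {
    stop("internal consistency: all-four set not within the any-condition set",
         call. = FALSE)
  }
  per_zone_time <- NULL
  if (!is.null(stress_records)) {
    per_zone_time <- do.call(rbind, lapply(names(stress_records), function(nm) {
      r <- stress_records[[nm]]
      data.frame(comparison = nm,
                 n_deg = sum(r$is_deg),
                 up = sum(r$is_deg & r$log2fc > 0),
                 down = sum(r$is_deg & r$log2fc < 0),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(
    zone_any_condition = sum(zone$any_condition),
    zone_all_four = all4,
    dz_preferred = sum(zone$dz_all4),
    ez_preferred = sum(zone$ez_all4),
    dz_core = sum(zone$core_dz),
    ez_core = sum(zone$core_ez),
    stress_responsive = sum(stress$responsive),
    stress_dz = sum(stress$dz_responsive),
    stress_ez = sum(stress$ez_responsive),
    timing_early_only = sum(stress$timing_global == "early-only", na.rm = TRUE),
    timing_sustained = sum(stress$timing_global == "sustained", na.rm = TRUE),
    timing_late = sum(stress$timing_global == "late", na.rm = TRUE),
    per_zone_time = per_zone_time
  )
  if (out$dz_preferred + out$ez_preferred != out$zone_all_four) {
    stop("internal consistency: DZ-preferred + EZ-preferred != all-four count",
         call. = FALSE)
  }
  structure(out, class = "deg_summary")
}

#' @export
print.deg_summary <- function(x, ...) {
  cat("Differentially expressed gene sets\n")
  cat(sprintf("  zone DEGs, >= 1 condition:   %6d\n", x$zone_any_condition))
  cat(sprintf("  zone DEGs, all 4 conditions: %6d (DZ-preferred %d + EZ-preferred %d)\n",
              x$zone_all_four, x$dz_preferred, x$ez_preferred))
  cat(sprintf("  core sets: DZ %d, EZ %d\n", x$dz_core, x$ez_core))
  cat(sprintf("  stress-responsive:           %6d (DZ %d, EZ %d)\n",
              x$stress_responsive, x$stress_dz, x$stress_ez))
  cat(sprintf("  timing: early-only %d, sustained %d, late %d\n",
              x$timing_early_only, x$timing_sustained, x$timing_late))
  if (!is.null(x$per_zone_time)) {
    for (i in seq_len(nrow(x$per_zone_time))) {
      cat(sprintf("    %-18s %4d DEGs (%d up, %d down)\n",
                  x$per_zone_time$comparison[i], x$per_zone_time$n_deg[i],
                  x$per_zone_time$up[i], x$per_zone_time$down[i]))
    }
  }
  invisible(x)
}

#' Full DEG classification of an expression table
#'
#' Runs the eight canonical comparisons ([default_comparisons()]) with the
#' standard three-part DEG rule (t-test p < `alpha`, BH q < `alpha`,
#' `|log2fc| >= fc_threshold`), classifies zone preference and stress
#' response, and summarizes the set counts.
#'
#' @inheritParams differential_expression
#' @inheritParams call_expressed
#' @return List of class `deg_classification` with elements `records` (named
#'   list of eight `deg_records`), `expressed`, `zone`, `stress`, `summary`.
#' @export
deg_classification <- function(table, pseudocount = 1, alpha = 0.05,
                               fc_threshold = 2, min_fpkm = 1, min_units = 1) {
  stopifnot(inherits(table, "expression_table"))
  expressed <- call_expressed(table, min_fpkm, min_units)
  cmp <- default_comparisons()
  records <- lapply(cmp$name, function(nm) {
    differential_expression(table, comparison = nm, pseudocount = pseudocount,
                            alpha = alpha, fc_threshold = fc_threshold,
                            expressed = expressed)
  })
  names(records) <- cmp$name
  zone <- classify_zone_preference(records[cmp$name[cmp$family == "zone"]])
  stress <- classify_stress_response(records[cmp$name[cmp$family == "stress"]])
  summary <- summarize_counts(zone, stress,
                              records[cmp$name[cmp$family == "stress"]])
  structure(list(records = records, expressed = expressed, zone = zone,
                 stress = stress, summary = summary),
            class = "deg_classification")
}

#' @export
print.deg_classification <- function(x, ...) {
  cat(sprintf("DEG classification: %d genes, %d expressed\n",
              length(x$expressed), sum(x$expressed)))
  print(x$summary)
  invisible(x)
}
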