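# Simulated zone x treatment x time FPKM tables with planted ground truth.

design_units <- function() {
  u <- expand.grid(time = c("0.5h", "3h"), treatment = c("CTL", "PEG"),
                   zone = c("DZ", "EZ"), stringsAsFactors = FALSE)
  u <- u[, c("zone", "treatment", "time")]
  u$unit <- paste(u$zone, u$treatment, u$time, sep = "_")
  u
}

#' Specification of a simulated expression experiment
#'
#' Describes a replicated FPKM table over the full 2 zone (DZ/EZ) x
#' 2 treatment (CTL/PEG) x 2 time (0.5h/3h) design, with planted
#' zone-preferred and stress-responsive gene sets of known log2 fold change.
#' Gene-wise baselines are log-normal (`2^N(baseline_log2_mean,
#' baseline_log2_sd)`); replicate noise is log-normal with sd
#' `replicate_log2_sd` on the log2 scale. Planted sets are disjoint by
#' construction: genes are assigned consecutively to DZ-preferred,
#' EZ-preferred, then stress-responsive blocks; the remainder are null.
#'
#' @param n_genes Total number of genes.
#' @param n_replicates Replicates per sampling unit (default 4).
#' @param baseline_log2_mean,baseline_log2_sd Log2-FPKM baseline distribution.
#' @param zone_effects Data frame with columns `zone` ("DZ" or "EZ"), `n`,
#'   and `log2fc` (> 0): sets with `log2fc`-fold higher expression in that
#'   zone, in every condition.
#' @param stress_effects Data frame with columns `zone`, `timing` (one of
#'   "early-only", "sustained", "late"), `n`, `log2fc` (signed): PEG response
#'   planted in the given zone at 0.5 h only, both times, or 3 h only.
#' @param replicate_log2_sd Replicate noise sd on the log2 scale.
#' @param seed RNG seed.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 5000, n_replicates = 4,
                                baseline_log2_mean = 5, baseline_log2_sd = 2,
                                zone_effects = data.frame(
                                  zone = c("DZ", "EZ"), n = c(100, 150),
                                  log2fc = c(3, 3)),
                                stress_effects = data.frame(
                                  zone = c("DZ", "EZ", "DZ", "EZ"),
                                  timing = c("early-only", "early-only",
                                             "sustained", "late"),
                                  n = c(25, 25, 25, 25),
                                  log2fc = c(3, 3, 3, -3)),
                                replicate_log2_sd = 0.5, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (!is.null(zone_effects) && nrow(zone_effects) > 0) {
    stopifnot(all(c("zone", "n", "log2fc") %in% names(zone_effects)),
              all(zone_effects$zone %in% c("DZ", "EZ")))
    if (anyDuplicated(zone_effects$zone)) {
      stop("at most one zone_effects row per zone (sets must be disjoint)",
           call. = FALSE)
    }
  }
  if (!is.null(stress_effects) && nrow(stress_effects) > 0) {
    stopifnot(all(c("zone", "timing", "n", "log2fc") %in% names(stress_effects)),
              all(stress_effects$zone %in% c("DZ", "EZ")),
              all(stress_effects$timing %in% c("early-only", "sustained", "late")))
  }
  planted <- sum(zone_effects$n %||% 0) + sum(stress_effects$n %||% 0)
  if (planted > n_genes) {
    stop("planted gene set sizes exceed `n_genes`", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 zone_effects = zone_effects, stress_effects = stress_effects,
                 replicate_log2_sd = replicate_log2_sd, seed = seed),
            class = "expression_sim_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a replicated FPKM expression table
#'
#' Draws the table described by an [expression_sim_spec()]: FPKM =
#' `2^(baseline + planted effects + replicate noise)`. Zone effects are added
#' to all columns of the preferred zone (so the DZ/EZ mean ratio is
#' `2^log2fc` in every condition); stress effects are added to the PEG
#' columns of the planted zone at the times implied by the timing class.
#' Bit-identical under a fixed spec seed.
#'
#' @param sim An [expression_sim_spec()].
#' @return An object of class `expression_table`: list with `fpkm` (gene x
#'   sample matrix, columns named `zone_treatment_time_Rrep`), `design` (one
#'   row per column), and `truth` (per-gene class, zone, timing and planted
#'   log2fc).
#' @export
simulate_expression_table <- function(sim) {
  stopifnot(inherits(sim, "expression_sim_spec"))
  units <- design_units()
  nrep <- sim$n_replicates
  design <- units[rep(seq_len(nrow(units)), each = nrep), ]
  design$replicate <- rep(seq_len(nrep), times = nrow(units))
  design$sample <- paste0(design$unit, "_R", design$replicate)
  rownames(design) <- NULL
  ng <- sim$n_genes
  genes <- sprintf("gene%05d", seq_len(ng))

  truth <- data.frame(gene_id = genes, class = "null",
                      zone = NA_character_, timing = NA_character_,
                      log2fc = 0, stringsAsFactors = FALSE)
  effects <- matrix(0, ng, nrow(design))
  nxt <- 1L
  ze <- sim$zone_effects
  if (!is.null(ze)) for (i in seq_len(nrow(ze))) {
    if (ze$n[i] == 0) next
    idx <- nxt:(nxt + ze$n[i] - 1L); nxt <- nxt + ze$n[i]
    cols <- design$zone == ze$zone[i]
    effects[idx, cols] <- effects[idx, cols] + ze$log2fc[i]
    truth$class[idx] <- paste0(ze$zone[i], "-preferred")
    truth$zone[idx] <- ze$zone[i]
    truth$log2fc[idx] <- ze$log2fc[i]
  }
  se <- sim$stress_effects
  if (!is.null(se)) for (i in seq_len(nrow(se))) {
    if (se$n[i] == 0) next
    idx <- nxt:(nxt + se$n[i] - 1L); nxt <- nxt + se$n[i]
    times <- switch(se$timing[i],
                    "early-only" = "0.5h", "late" = "3h",
                    "sustained" = c("0.5h", "3h"))
    cols <- design$zone == se$zone[i] & design$treatment == "PEG" &
      design$time %in% times
    effects[idx, cols] <- effects[idx, cols] + se$log2fc[i]
    truth$class[idx] <- "stress-responsive"
    truth$zone[idx] <- se$zone[i]
    truth$timing[idx] <- se$timing[i]
    truth$log2fc[idx] <- se$log2fc[i]
  }

  mats <- with_seed(sim$seed, {
    base <- stats::rnorm(ng, sim$baseline_log2_mean, sim$baseline_log2_sd)
    noise <- if (sim$replicate_log2_sd > 0) {
      matrix(stats::rnorm(ng * nrow(design), 0, sim$replicate_log2_sd),
             ng, nrow(design))
    } else matrix(0, ng, nrow(design))
    list(base = base, noise = noise)
  })
  log2fpkm <- mats$base + effects + mats$noise
  fpkm <- 2^log2fpkm
  dimnames(fpkm) <- list(genes, design$sample)
  structure(list(fpkm = fpkm, design = design, truth = truth),
            class = "expression_table")
}

#' Construct an expression table from an FPKM matrix
#'
#' Wraps a gene x sample FPKM matrix whose column names encode the sampling
#' unit as `zone_treatment_time_Rreplicate` (e.g. `DZ_CTL_0.5h_R1`) into the
#' container used by the differential-expression functions. The design must
#' be the complete 2x2x2 layout with an equal replicate count per unit and no
#' negative values.
#'
#' @param fpkm Numeric matrix, genes in rows, samples in columns.
#' @return An `expression_table`.
#' @export
expression_table <- function(fpkm) {
  stopifnot(is.matrix(fpkm), !is.null(colnames(fpkm)), !is.null(rownames(fpkm)))
  if (any(fpkm < 0)) stop("FPKM values must be >= 0", call. = FALSE)
  parts <- strsplit(colnames(fpkm), "_", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("column names must be zone_treatment_time_Rrep", call. = FALSE)
  }
  design <- data.frame(zone = vapply(parts, `[`, "", 1L),
                       treatment = vapply(parts, `[`, "", 2L),
                       time = vapply(parts, `[`, "", 3L),
                       replicate = as.integer(sub("^R", "",
                                                  vapply(parts, `[`, "", 4L))),
                       stringsAsFactors = FALSE)
  design$unit <- paste(design$zone, design$treatment, design$time, sep = "_")
  design$sample <- colnames(fpkm)
  expected <- design_units()$unit
  tab <- table(factor(design$unit, levels = expected))
  if (any(tab == 0)) stop("incomplete design: missing sampling units", call. = FALSE)
  if (length(unique(tab)) != 1L) {
    stop("unequal replicate counts across sampling units", call. = FALSE)
  }
  structure(list(fpkm = fpkm, design = design, truth = NULL),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("Expression table: %d genes x %d samples (%d units x %d replicates)\n",
              nrow(x$fpkm), ncol(x$fpkm), length(unique(x$design$unit)),
              max(x$design$replicate)))
  if (!is.null(x$truth)) {
    cat("  planted truth: ", paste(names(table(x$truth$class)),
                                   table(x$truth$class), collapse = ", "), "\n")
  }
  invisible(x)
}
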