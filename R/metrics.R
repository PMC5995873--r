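#' Porosity of a segmented volume
#'
#' The material fraction is the number of material voxels (fibers,
#' particles or both) over the total voxel count; porosity is its
#' complement. Both are reported as percentages and sum to 100 exactly.
#'
#' @param mask a material [PhaseMask-class] (or logical 3D array).
#' @return list with `porosity` and `materialFraction` (percent).
#' @examples
#' m <- array(FALSE, c(32, 32, 32)); m[1:16, , ] <- TRUE
#' porosity(m)$porosity  # 50
#' @export
porosity <- function(mask) {
  if (is(mask, "PhaseMask")) mask <- volumeData(mask)
  stopifnot(is.logical(mask))
  if (length(mask) == 0) stop("empty grid")
  f <- sum(mask) / length(mask)
  list(porosity = 100 * (1 - f), materialFraction = 100 * f)
}

# the reporting tiers used alongside Tukey-adjusted p values
significanceTier <- function(p) {
  ifelse(p < 0.05, "*",
         ifelse(p < 0.1, "**",
                ifelse(p < 0.3, "***",
                       ifelse(p > 0.8, "N.S.", "n.s."))))
}

#' One-way ANOVA with Tukey HSD post hoc comparison
#'
#' Compares a numeric measurement (porosity, diameter, count, ...) across
#' sample groups: one-way ANOVA for the omnibus F test, then all-pairs
#' Tukey HSD adjusted p values via the studentized-range distribution
#' (Tukey–Kramer for unbalanced groups). Pairwise significance is flagged
#' at `alpha`, and the reporting tiers `*` p < 0.05, `**` p < 0.1, `***`
#' p < 0.3 and `N.S.` p > 0.8 are attached as labels only — no decision in
#' the package depends on them.
#'
#' @param samples named list of numeric vectors, one per group (>= 2
#'   groups, each n >= 2).
#' @param alpha family-wise significance level (default 0.05).
#' @return list: `groups` (n, mean, SD per group), `anova` (`F`, `p`),
#'   `pairwise` (per pair: mean difference, adjusted p, `significant`,
#'   `tier`).
#' @examples
#' groupCompare(list(a = c(77.1, 76.9, 77.6), b = c(72.3, 71.5, 73.1)))
#' @export
groupCompare <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need at least two groups")
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("groups must be named")
  n <- vapply(samples, length, integer(1))
  if (any(n < 2L))
    stop("each group needs n >= 2 (got n = ",
         paste(n, collapse = ", "), ")")
  df <- data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(names(samples), n), levels = names(samples)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  Fval <- tab["group", "F value"]
  pval <- tab["group", "Pr(>F)"]
  if (!is.finite(Fval)) { Fval <- 0; pval <- 1 }   # zero within-group MS
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pw <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                   pAdjusted = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha,
                   tier = significanceTier(tk[, "p adj"]),
                   row.names = NULL)
  list(
    groups = data.frame(group = names(samples), n = n,
                        mean = vapply(samples, mean, numeric(1)),
                        sd = vapply(samples, stats::sd, numeric(1)),
                        row.names = NULL),
    anova = list(F = Fval, p = pval),
    pairwise = pw,
    alpha = alpha
  )
}

#' Cation ratio of a calcium phosphate formula
#'
#' Computes Ca / (P + Si) from per-formula-unit stoichiometric counts.
#' Stoichiometric hydroxyapatite, Ca10(PO4)6(OH)2, gives 10/6 = 1.67; the
#' silicate-substituted precursor Ca10(PO4)5.2(SiO4)0.8(OH)1.2 gives the
#' same ratio since silicate substitutes for phosphate one-for-one.
#'
#' @param formula named numeric of stoichiometric counts; `Ca` and `P`
#'   required, `Si` optional (treated as 0 if absent).
#' @param digits decimal places for the displayed value (default 2;
#'   `NULL` returns full precision).
#' @return the ratio.
#' @examples
#' cationRatio(c(Ca = 10, P = 6))            # 1.67
#' cationRatio(c(Ca = 10, P = 5.2, Si = 0.8)) # 1.67
#' @export
cationRatio <- function(formula, digits = 2) {
  if (!all(c("Ca", "P") %in% names(formula)))
    stop("formula must name Ca and P counts")
  si <- if ("Si" %in% names(formula)) formula[["Si"]] else 0
  if (any(c(formula[["Ca"]], formula[["P"]], si) < 0) ||
      formula[["P"]] + si <= 0)
    stop("counts must be positive and P + Si > 0")
  r <- formula[["Ca"]] / (formula[["P"]] + si)
  if (is.null(digits)) r else round(r, digits)
}

#' Assemble a per-sample analysis report
#'
#' Bundles whatever stages were run — segmentation thresholds, porosity,
#' particle table and size bins, fiber orientation/diameter histograms,
#' group statistics — into one list; missing stages are simply omitted.
#' Use [writeReport()] to serialize it as JSON plus CSV tables.
#'
#' @param sample sample name.
#' @param segmentation result of [segmentPhases()] (optional).
#' @param porosity result of [porosity()] (optional).
#' @param fibers skeleton-point data.frame from [analyzeFibers()]
#'   (optional).
#' @param particles data.frame from [particleTable()] (optional).
#' @param groups result of [groupCompare()] (optional).
#' @param azimuthBinWidth,latitudeBinWidth histogram bin widths, degrees.
#' @return a named list (class `scaffoldReport`).
#' @export
buildReport <- function(sample = "sample", segmentation = NULL,
                        porosity = NULL, fibers = NULL, particles = NULL,
                        groups = NULL, azimuthBinWidth = 10,
                        latitudeBinWidth = 10) {
  if (is.null(segmentation) && is.null(porosity) && is.null(fibers) &&
      is.null(particles) && is.null(groups))
    stop("at least one completed stage is required")
  rep <- list(sample = sample)
  if (!is.null(segmentation))
    rep$thresholds <- as.list(segmentation$thresholds)
  if (!is.null(porosity)) rep$porosity <- porosity
  if (!is.null(fibers)) {
    rep$fibers <- list(
      nSkeletonPoints = nrow(fibers),
      nValid = sum(fibers$valid),
      azimuthHistogram = orientationHistogram(fibers, "azimuth",
                                              azimuthBinWidth),
      latitudeHistogram = orientationHistogram(fibers, "latitude",
                                               latitudeBinWidth),
      diameterDistribution = diameterDistribution(fibers),
      medianDiameter = stats::median(fibers$diameter[fibers$valid])
    )
  }
  if (!is.null(particles)) {
    rep$particles <- list(
      nAggregates = nrow(particles),
      nInterior = sum(!particles$onBorder),
      table = particles,
      sizeDistribution = particleSizeDistribution(particles)
    )
  }
  if (!is.null(groups)) rep$groupStats <- groups
  class(rep) <- c("scaffoldReport", "list")
  rep
}

#' Write a report bundle to disk
#'
#' Serializes the report as `report.json` plus one CSV per tabular section
#' (particle table, size distribution, orientation histograms, diameter
#' distribution, pairwise statistics).
#'
#' @param report a list from [buildReport()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  writeCsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  if (!is.null(report$fibers)) {
    writeCsv(report$fibers$azimuthHistogram, "azimuth_histogram.csv")
    writeCsv(report$fibers$latitudeHistogram, "latitude_histogram.csv")
    writeCsv(report$fibers$diameterDistribution, "diameter_distribution.csv")
  }
  if (!is.null(report$particles)) {
    writeCsv(report$particles$table, "particle_table.csv")
    writeCsv(report$particles$sizeDistribution, "particle_sizes.csv")
  }
  if (!is.null(report$groupStats))
    writeCsv(report$groupStats$pairwise, "pairwise_stats.csv")
  invisible(dir)
}
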