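#' Default ERP score tables
#'
#' Documented stand-in tables mapping each feature to a multiplicative
#' retrotransposition-impact factor R in `[0, 1]`. Each table is
#' piecewise linear with anchors: factor 1.0 at the reference feature
#' value (consensus-identical body, 50-base pure tail, 0-base unique
#' region, 0% disruption), 0.5 at the corresponding dichotomous-key
#' threshold, and the floor beyond twice the threshold (below half the
#' threshold for the A-tail, whose impact runs in the opposite
#' direction). The floor (default 1e-6) is the minimum ERP assigned to
#' any structurally intact locus. User-measured tables can replace any
#' of the four via [loadScoreTables()].
#'
#' @param floor Minimum ERP (default 1e-6).
#' @return A [ScoreTables-class] object.
#' @examples
#' defaultScoreTables()
#' @export
defaultScoreTables <- function(floor = 1e-6) {
  new("ScoreTables",
    divergence = data.frame(value = c(0, 5, 10, 20),
                            R = c(1, 0.75, 0.5, floor)),
    aTail = data.frame(value = c(0, 10, 20, 50),
                       R = c(floor, floor, 0.5, 1)),
    unique = data.frame(value = c(0, 20, 40),
                        R = c(1, 0.5, floor)),
    disruption = data.frame(value = c(0, 10, 20),
                            R = c(1, 0.5, floor)),
    floor = floor)
}

## piecewise-linear lookup with clamping at both ends
.lookupR <- function(tab, v) {
  stats::approx(tab$value, tab$R, xout = v, rule = 2)$y
}

#' Load (possibly partial) ERP score tables from a TSV config file
#'
#' The file is tab-separated with header `feature  value  R`. `feature`
#' is one of `divergence`, `a_tail`, `unique`, `disruption`; the rows of
#' each feature form its piecewise-linear table. An optional row with
#' feature `floor` (value ignored) sets the ERP floor. Features without
#' rows keep the defaults, so a file can override a single table. The
#' result is validated: every R must lie in `[0, 1]` and each table must
#' be monotone in the direction its feature acts (offending rows are
#' reported).
#'
#' @param path Config file, or `NULL` for the pure defaults.
#' @param defaults Base tables to override (default
#'   [defaultScoreTables()]).
#' @return A validated [ScoreTables-class].
#' @export
loadScoreTables <- function(path = NULL, defaults = defaultScoreTables()) {
  if (is.null(path)) return(defaults)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature", "value", "R")
  if (!all(need %in% colnames(df)))
    stop("score-table config must have columns: ", paste(need, collapse = ", "))
  slotFor <- c(divergence = "divergence", a_tail = "aTail",
               unique = "unique", disruption = "disruption")
  unknown <- setdiff(unique(df$feature), c(names(slotFor), "floor"))
  if (length(unknown))
    stop("unknown feature(s) in score-table config: ",
         paste(unknown, collapse = ", "))
  out <- defaults
  fl <- df[df$feature == "floor", , drop = FALSE]
  if (nrow(fl)) out@floor <- fl$R[nrow(fl)]
  for (f in intersect(unique(df$feature), names(slotFor))) {
    tab <- df[df$feature == f, c("value", "R")]
    tab <- tab[order(tab$value), , drop = FALSE]
    rownames(tab) <- NULL
    slot(out, slotFor[[f]]) <- tab
  }
  validObject(out)
  out
}

#' Apply the dichotomous classification key
#'
#' Bins each structurally intact locus by the four criteria: divergence
#' below the first breakpoint (best bin), between the breakpoints
#' (middle bin), or above the second (retrotranspositionally inactive);
#' A-tail pass iff length >= `aTailMin`; unique pass iff length <=
#' `uniqueMax`; disruption pass iff <= `disruptionMax` (all inclusive).
#' A locus is potentially active iff its divergence is at or below the
#' upper breakpoint and all three other criteria pass.
#'
#' @param features One row (or several) of [extractFeatures()] output,
#'   or any data.frame-like with columns `divergence_pct`, `a_tail_len`,
#'   `unique_len`, `a_tail_disruption_pct`, `structure_ok`.
#' @param cfg A [keyConfig()].
#' @return A [S4Vectors::DataFrame]: `divergence_bin` (`"lt5"`,
#'   `"5to10"`, `"gt10"` under default breakpoints), `a_tail_pass`,
#'   `unique_pass`, `disruption_pass`, `potentially_active`.
#' @examples
#' f <- S4Vectors::DataFrame(divergence_pct = 3, a_tail_len = 25L,
#'                           unique_len = 10L, a_tail_disruption_pct = 4,
#'                           structure_ok = TRUE)
#' applyKey(f, keyConfig())
#' @export
applyKey <- function(features, cfg = keyConfig()) {
  stopifnot(is(cfg, "KeyConfig"))
  if (any(!features$structure_ok))
    stop("filtered locus has no key result: apply the structural filter first")
  b <- cfg@divergenceBins
  d <- features$divergence_pct
  binLabels <- c(sprintf("lt%g", b[1]), sprintf("%gto%g", b[1], b[2]),
                 sprintf("gt%g", b[2]))
  bin <- ifelse(d < b[1], binLabels[1],
                ifelse(d <= b[2], binLabels[2], binLabels[3]))
  aPass <- features$a_tail_len >= cfg@aTailMin
  uPass <- features$unique_len <= cfg@uniqueMax
  pPass <- features$a_tail_disruption_pct <= cfg@disruptionMax
  S4Vectors::DataFrame(
    divergence_bin = bin,
    a_tail_pass = aPass, unique_pass = uPass, disruption_pass = pPass,
    potentially_active = d <= b[2] & aPass & uPass & pPass)
}

#' Compute the estimated retrotransposition potential (ERP)
#'
#' The ERP of a structurally intact locus is the product of the four
#' per-feature R factors looked up in the score tables, clamped below at
#' the table floor:
#' `ERP = max(floor, R_div(d) * R_tail(L) * R_unique(u) * R_disr(p))`.
#' A locus at the reference value of all four tables scores exactly
#' 1.00. In genome-wide mode (`bBoxRequired = TRUE`) loci without a
#' B-box are refused, mirroring the B-box gate of the genome-wide scan.
#'
#' @param features [extractFeatures()] output rows (must be
#'   structurally intact).
#' @param tables A [ScoreTables-class] (default [defaultScoreTables()]).
#' @param bBoxRequired If `TRUE`, error when any locus lacks a B-box.
#' @return Numeric vector of ERP scores in `[floor, 1]`.
#' @examples
#' f <- S4Vectors::DataFrame(divergence_pct = 0, a_tail_len = 50L,
#'                           unique_len = 0L, a_tail_disruption_pct = 0,
#'                           structure_ok = TRUE, has_b_box = TRUE)
#' erpScore(f)  # 1.00, the ideal element
#' @export
erpScore <- function(features, tables = defaultScoreTables(),
                     bBoxRequired = FALSE) {
  stopifnot(is(tables, "ScoreTables"))
  validObject(tables)
  if (any(!features$structure_ok))
    stop("filtered locus has no ERP: apply the structural filter first")
  if (bBoxRequired && any(!features$has_b_box))
    stop("B-box gate: locus without a B-box cannot be scored in ",
         "genome-wide mode")
  r <- .lookupR(tables@divergence, features$divergence_pct) *
    .lookupR(tables@aTail, features$a_tail_len) *
    .lookupR(tables@unique, features$unique_len) *
    .lookupR(tables@disruption, features$a_tail_disruption_pct)
  pmax(tables@floor, r)
}

#' Classify ERP scores against the standard thresholds
#'
#' @param erp Numeric ERP scores.
#' @param thresholds Ascending thresholds (default `c(0.10, 0.20, 0.50)`).
#' @return Character vector: `"<0.1"` or the highest threshold met as
#'   `">=0.1"`, `">=0.2"`, `">=0.5"`.
#' @export
erpThresholdClass <- function(erp, thresholds = c(0.10, 0.20, 0.50)) {
  thresholds <- sort(thresholds)
  labs <- c(sprintf("<%g", thresholds[1]), sprintf(">=%g", thresholds))
  idx <- rowSums(outer(erp, thresholds, `>=`)) + 1L
  labs[idx]
}

#' Key bins, ERP and threshold class for a whole cohort
#'
#' Convenience wrapper combining [applyKey()], [erpScore()] and
#' [erpThresholdClass()] over the structurally intact subset of a
#' feature table. Rejected loci are dropped (they have no key result).
#'
#' @param features Full [extractFeatures()] output.
#' @param tables A [ScoreTables-class].
#' @param cfg A [keyConfig()].
#' @param thresholds ERP thresholds for classification.
#' @param bBoxRequired Genome-wide B-box gate: loci without a B-box are
#'   excluded before scoring.
#' @return [S4Vectors::DataFrame]: the intact feature rows with key
#'   bins, `erp` and `threshold_class` columns appended.
#' @export
scoreCohort <- function(features, tables = defaultScoreTables(),
                        cfg = keyConfig(), thresholds = c(0.10, 0.20, 0.50),
                        bBoxRequired = FALSE) {
  keep <- features$structure_ok
  if (bBoxRequired) keep <- keep & features$has_b_box
  f <- features[keep, , drop = FALSE]
  if (nrow(f) == 0L) {
    out <- f
    out$erp <- numeric(0)
    out$threshold_class <- character(0)
    return(out)
  }
  key <- applyKey(f, cfg)
  erp <- erpScore(f, tables, bBoxRequired = bBoxRequired)
  cbind(f, key, S4Vectors::DataFrame(
    erp = erp, threshold_class = erpThresholdClass(erp, thresholds)))
}
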