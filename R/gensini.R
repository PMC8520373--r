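#' Coronary segment coefficient table
#'
#' The fixed Gensini location multipliers: left main (LM) 5; proximal LAD
#' and proximal LCX 2.5; mid LAD 1.5; distal LAD, distal LCX, obtuse
#' marginal, RCA (proximal/mid/distal) and posterior descending 1; second
#' diagonal 0.5. LM lesions count toward both the LAD and LCX vessels.
#'
#' @return Named numeric vector of segment coefficients.
#' @export
gensini_coefficients <- function() {
  c(LM = 5, LAD_PROX = 2.5, LCX_PROX = 2.5, LAD_MID = 1.5,
    LAD_DIST = 1, LCX_DIST = 1, OM = 1,
    RCA_PROX = 1, RCA_MID = 1, RCA_DIST = 1, PDA = 1, DIAG2 = 0.5)
}

# parent vessel(s) of each segment (LM feeds both LAD and LCX)
segment_vessels <- function() {
  list(LM = c("LAD", "LCX"),
       LAD_PROX = "LAD", LAD_MID = "LAD", LAD_DIST = "LAD", DIAG2 = "LAD",
       LCX_PROX = "LCX", LCX_DIST = "LCX", OM = "LCX",
       RCA_PROX = "RCA", RCA_MID = "RCA", RCA_DIST = "RCA", PDA = "RCA")
}

#' Stenosis severity points
#'
#' Maps percent diameter stenosis to the Gensini severity points
#' \{1, 2, 4, 8, 16, 32\}: points double at the 25, 50, 75, 90 and 100
#' percent thresholds (right-closed buckets); 0 percent (no lesion) scores
#' 0.
#'
#' @param pct Percent stenosis in \[0, 100\] (vectorized).
#' @return Integer points.
#' @examples
#' stenosis_points(c(0, 20, 50, 72, 80, 95, 100))
#' @export
stenosis_points <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100))
    stopf("stenosis percent must lie in [0, 100]")
  pts <- integer(length(pct))
  pts[pct > 0 & pct <= 25] <- 1L
  pts[pct > 25 & pct <= 50] <- 2L
  pts[pct > 50 & pct <= 75] <- 4L
  pts[pct > 75 & pct <= 90] <- 8L
  pts[pct > 90 & pct < 100] <- 16L
  pts[pct == 100] <- 32L
  pts
}

check_lesions <- function(lesions) {
  if (!is.data.frame(lesions) ||
      !all(c("segment", "stenosis_pct") %in% names(lesions)))
    stopf("`lesions` must be a data frame with columns segment, stenosis_pct")
  unknown <- setdiff(unique(as.character(lesions$segment)),
                     names(gensini_coefficients()))
  if (length(unknown))
    stopf("unknown coronary segment(s): %s", paste(unknown, collapse = ", "))
  if (any(lesions$stenosis_pct < 0 | lesions$stenosis_pct > 100))
    stopf("stenosis percent must lie in [0, 100]")
  lesions
}

#' Gensini coronary severity score
#'
#' Total = sum over lesions of severity points ([stenosis_points()]) times
#' the segment's location coefficient. An empty lesion list scores 0.
#'
#' @param lesions Data frame with columns `segment` (names as in
#'   [gensini_coefficients()]) and `stenosis_pct`.
#' @return An object of class `gensini_result`: list with `total` and
#'   `per_lesion` (data frame of segment, stenosis_pct, points, coefficient,
#'   contribution).
#' @examples
#' gensini_score(data.frame(segment = "LM", stenosis_pct = 100))$total  # 160
#' @export
gensini_score <- function(lesions) {
  if (is.null(lesions) || nrow(lesions) == 0L) {
    return(structure(list(total = 0,
                          per_lesion = data.frame(segment = character(0),
                                                  stenosis_pct = numeric(0),
                                                  points = integer(0),
                                                  coefficient = numeric(0),
                                                  contribution = numeric(0))),
                     class = "gensini_result"))
  }
  lesions <- check_lesions(lesions)
  coefs <- gensini_coefficients()[as.character(lesions$segment)]
  pts <- stenosis_points(lesions$stenosis_pct)
  per <- data.frame(segment = as.character(lesions$segment),
                    stenosis_pct = lesions$stenosis_pct,
                    points = pts, coefficient = as.numeric(coefs),
                    contribution = pts * as.numeric(coefs))
  structure(list(total = sum(per$contribution), per_lesion = per),
            class = "gensini_result")
}

#' @export
print.gensini_result <- function(x, ...) {
  cat(sprintf("<gensini_result> total = %g over %d lesion(s)\n",
              x$total, nrow(x$per_lesion)))
  invisible(x)
}

#' Classify the number of stenosed coronary vessels (NSCV)
#'
#' A vessel (LAD, LCX or RCA) counts as stenosed when any lesion on its
#' segments reaches `threshold_pct`; a left-main lesion at threshold marks
#' both LAD and LCX (two-vessel disease). The category follows the count:
#' none, single, double, multi.
#'
#' @param lesions Lesion data frame as in [gensini_score()].
#' @param threshold_pct Stenosis threshold in percent (default 50, the
#'   angiographic disease definition).
#' @return An object of class `vessel_classification`: list with
#'   `stenosed_vessels` (character subset of LAD/LCX/RCA), `category`
#'   (factor level among none/single/double/multi), `threshold_pct`.
#' @examples
#' classify_nscv(data.frame(segment = "LM", stenosis_pct = 60))$category
#' @export
classify_nscv <- function(lesions, threshold_pct = 50) {
  vessels <- character(0)
  if (!is.null(lesions) && nrow(lesions) > 0L) {
    lesions <- check_lesions(lesions)
    hit <- lesions$stenosis_pct >= threshold_pct
    vmap <- segment_vessels()
    vessels <- sort(unique(unlist(vmap[as.character(lesions$segment[hit])])))
  }
  cats <- c("none", "single", "double", "multi")
  structure(list(stenosed_vessels = vessels,
                 category = factor(cats[min(length(vessels), 3L) + 1L],
                                   levels = cats),
                 threshold_pct = threshold_pct),
            class = "vessel_classification")
}

#' Score a lesion report table
#'
#' Convenience wrapper for CSV lesion reports with multiple patients:
#' computes the Gensini total and NSCV category per patient.
#'
#' @param lesions Data frame with columns `patient_id`, `segment`,
#'   `stenosis_pct` (e.g. from [read_lesions_csv()]).
#' @param threshold_pct NSCV stenosis threshold.
#' @return Data frame with one row per patient: `patient_id`, `gensini`,
#'   `nscv_category`, `n_stenosed_vessels`.
#' @export
score_lesion_report <- function(lesions, threshold_pct = 50) {
  stopifnot(is.data.frame(lesions), "patient_id" %in% names(lesions))
  ids <- unique(lesions$patient_id)
  do.call(rbind, lapply(ids, function(id) {
    sub <- lesions[lesions$patient_id == id, , drop = FALSE]
    cls <- classify_nscv(sub, threshold_pct)
    data.frame(patient_id = id, gensini = gensini_score(sub)$total,
               nscv_category = as.character(cls$category),
               n_stenosed_vessels = length(cls$stenosed_vessels))
  }))
}

#' Read a lesion report CSV
#'
#' Expected columns: `patient_id`, `segment`, `stenosis_pct`.
#'
#' @param path CSV file path.
#' @return Data frame of lesions.
#' @export
read_lesions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "segment", "stenosis_pct")
  if (!all(need %in% names(df)))
    stopf("lesion CSV must have columns %s", paste(need, collapse = ", "))
  df
}
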