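# Object-level segmentation metrics: Dice, Hausdorff, size-weighted
# bidirectional object-Dice (OD) and object-Hausdorff (OH) following the
# gland-segmentation challenge definitions, plus multi-observer agreement.

#' Dice coefficient of two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`; defined as 1 when both masks are empty.
#' @param a,b logical matrices of equal dimensions.
#' @return numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Hausdorff distance between two pixel point sets
#'
#' Maximum of the two directed sup-inf Euclidean distances.
#' @param a,b n x 2 matrices of (row, col) coordinates; both non-empty.
#' @return distance in pixels.
#' @export
hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("hausdorff() undefined for empty point sets")
  cpp_hausdorff(matrix(as.numeric(a), nrow(a), 2L),
                matrix(as.numeric(b), nrow(b), 2L))
}

# boundary pixel coordinates of one object (4-neighbour-outside rule,
# image border counts as outside)
object_boundary_points <- function(instances, label) {
  b <- object_boundary_mask(instances * (instances == label))
  which(b, arr.ind = TRUE)
}

# pixel-overlap table between two label maps: data.frame(s, g, n) over
# co-occurring positive labels
overlap_table <- function(S, G) {
  idx <- S > 0L & G > 0L
  if (!any(idx)) return(data.frame(s = integer(0), g = integer(0),
                                   n = integer(0)))
  key <- paste(S[idx], G[idx])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  data.frame(s = as.integer(parts[, 1]), g = as.integer(parts[, 2]),
             n = as.integer(tab))
}

#' Match objects between two instance segmentations
#'
#' Each object in `S` is matched to the `G` object of maximal pixel overlap
#' (ties to the lowest label), and symmetrically; objects with zero overlap
#' are additionally matched, for the object-Hausdorff metric, to the object
#' on the other side with minimal boundary Hausdorff distance.
#'
#' @param S,G integer instance label maps of equal dimensions.
#' @return list with `s_labels`, `g_labels`, `s_match`/`g_match` (overlap
#'   matches; 0 = unmatched), `s_match_oh`/`g_match_oh` (always matched when
#'   the other side is non-empty), and `flagged` (TRUE when a side is
#'   empty).
#' @export
match_objects <- function(S, G) {
  storage.mode(S) <- "integer"; storage.mode(G) <- "integer"
  if (!all(dim(S) == dim(G))) stop("instance maps differ in dimensions")
  s_labels <- sort(setdiff(unique(as.vector(S)), 0L))
  g_labels <- sort(setdiff(unique(as.vector(G)), 0L))
  ov <- overlap_table(S, G)
  best_of <- function(labels, own, other) {
    vapply(labels, function(l) {
      rows <- ov[ov[[own]] == l, , drop = FALSE]
      if (!nrow(rows)) return(0L)
      rows <- rows[order(-rows$n, rows[[other]]), , drop = FALSE]
      rows[[other]][1]
    }, integer(1))
  }
  s_match <- best_of(s_labels, "s", "g")
  g_match <- best_of(g_labels, "g", "s")

  nearest_by_boundary <- function(l, own_map, other_map, other_labels) {
    bp <- object_boundary_points(own_map, l)
    d <- vapply(other_labels, function(m)
      hausdorff(bp, object_boundary_points(other_map, m)), numeric(1))
    other_labels[which.min(d)]
  }
  s_match_oh <- s_match; g_match_oh <- g_match
  if (length(g_labels))
    for (i in which(s_match == 0L))
      s_match_oh[i] <- nearest_by_boundary(s_labels[i], S, G, g_labels)
  if (length(s_labels))
    for (j in which(g_match == 0L))
      g_match_oh[j] <- nearest_by_boundary(g_labels[j], G, S, s_labels)

  list(s_labels = s_labels, g_labels = g_labels,
       s_match = s_match, g_match = g_match,
       s_match_oh = s_match_oh, g_match_oh = g_match_oh,
       flagged = length(s_labels) == 0L || length(g_labels) == 0L)
}

#' Object-Dice between two instance segmentations
#'
#' Size-weighted bidirectional form: with `w_i = |S_i| / sum_k |S_k|` and
#' symmetrically for `G`,
#' `OD = 1/2 * (sum_i w_i Dice(S_i, G_match(i)) + sum_j w~_j Dice(G_j, S_match(j)))`.
#' Unmatched objects contribute a Dice of 0; two empty maps give 1.
#'
#' @param S,G integer instance label maps.
#' @param matching optional pre-computed [match_objects()] result.
#' @return numeric in \[0, 1\].
#' @export
object_dice <- function(S, G, matching = NULL) {
  if (is.null(matching)) matching <- match_objects(S, G)
  m <- matching
  if (!length(m$s_labels) && !length(m$g_labels)) return(1)
  half <- function(A, B, labels, match) {
    if (!length(labels)) return(0)
    areas <- vapply(labels, function(l) sum(A == l), numeric(1))
    w <- areas / sum(areas)
    d <- vapply(seq_along(labels), function(i) {
      if (match[i] == 0L) return(0)
      dice(A == labels[i], B == match[i])
    }, numeric(1))
    sum(w * d)
  }
  0.5 * (half(S, G, m$s_labels, m$s_match) +
         half(G, S, m$g_labels, m$g_match))
}

#' Object-Hausdorff between two instance segmentations
#'
#' Size-weighted bidirectional sum of per-matched-pair boundary Hausdorff
#' distances, mirroring the object-Dice weighting. Objects without pixel
#' overlap are paired with the nearest object by boundary Hausdorff.
#' Undefined (NA, with attribute `flagged`) when either side has no
#' objects; two identical maps give 0.
#'
#' @inheritParams object_dice
#' @return distance in pixels, or NA when flagged undefined.
#' @export
object_hausdorff <- function(S, G, matching = NULL) {
  if (is.null(matching)) matching <- match_objects(S, G)
  m <- matching
  if (!length(m$s_labels) && !length(m$g_labels)) return(0)
  if (m$flagged) return(structure(NA_real_, flagged = TRUE))
  half <- function(A, B, labels, match_oh) {
    areas <- vapply(labels, function(l) sum(A == l), numeric(1))
    w <- areas / sum(areas)
    h <- vapply(seq_along(labels), function(i)
      hausdorff(object_boundary_points(A, labels[i]),
                object_boundary_points(B, match_oh[i])), numeric(1))
    sum(w * h)
  }
  0.5 * (half(S, G, m$s_labels, m$s_match_oh) +
         half(G, S, m$g_labels, m$g_match_oh))
}

#' Per-ROI object metric report
#'
#' @param pred,truth lists of instance label maps (parallel, one per ROI).
#' @param roi_ids optional ROI identifiers.
#' @return an `ObjectMetricReport`: data.frame `per_roi` (roi, od, oh) plus
#'   aggregate `od_mean`, `od_sd`, `oh_mean`, `oh_sd` (mean +/- SD over
#'   ROIs, NA-flagged ROIs excluded from the OH aggregate).
#' @export
object_metric_report <- function(pred, truth, roi_ids = NULL) {
  stopifnot(length(pred) == length(truth))
  if (is.null(roi_ids)) roi_ids <- as.character(seq_along(pred))
  od <- numeric(length(pred)); oh <- numeric(length(pred))
  for (i in seq_along(pred)) {
    m <- match_objects(pred[[i]], truth[[i]])
    od[i] <- object_dice(pred[[i]], truth[[i]], m)
    oh[i] <- object_hausdorff(pred[[i]], truth[[i]], m)
  }
  per_roi <- data.frame(roi = roi_ids, od = od, oh = oh,
                        stringsAsFactors = FALSE)
  structure(list(per_roi = per_roi,
                 od_mean = mean(od), od_sd = stats::sd(od),
                 oh_mean = mean(oh, na.rm = TRUE),
                 oh_sd = stats::sd(oh, na.rm = TRUE)),
            class = "ObjectMetricReport")
}

#' @export
print.ObjectMetricReport <- function(x, ...) {
  cat(sprintf("<ObjectMetricReport: %d ROI(s)>\n", nrow(x$per_roi)))
  cat(sprintf("  OD %.3f +/- %.3f   OH %.2f +/- %.2f px\n",
              x$od_mean, ifelse(is.na(x$od_sd), 0, x$od_sd),
              x$oh_mean, ifelse(is.na(x$oh_sd), 0, x$oh_sd)))
  invisible(x)
}

#' Write an object metric report to CSV
#'
#' Per-ROI rows followed by an `aggregate` row holding mean and SD.
#' @param report an [object_metric_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report_csv <- function(report, path) {
  df <- report$per_roi
  agg <- data.frame(roi = "mean_sd",
                    od = report$od_mean, oh = report$oh_mean,
                    stringsAsFactors = FALSE)
  df2 <- rbind(cbind(df, od_sd = NA_real_, oh_sd = NA_real_),
               cbind(agg, od_sd = report$od_sd, oh_sd = report$oh_sd))
  utils::write.csv(df2, path, row.names = FALSE)
  invisible(path)
}

#' Multi-observer pairwise agreement
#'
#' Computes OD/OH for every unordered pair of observers on every ROI and
#' averages over pairs and ROIs.
#'
#' @param annotations list (one element per observer) of lists of instance
#'   label maps (one per ROI, aligned across observers).
#' @return an `ObserverAgreementReport`: data.frame `pairwise` (observer_a,
#'   observer_b, od, oh averaged over ROIs) plus `od_mean` / `oh_mean`
#'   averaged over all pairs.
#' @export
pairwise_agreement <- function(annotations) {
  n <- length(annotations)
  if (n < 2L) stop("pairwise agreement needs at least 2 observers")
  n_roi <- length(annotations[[1]])
  for (a in annotations)
    if (length(a) != n_roi) stop("observers have differing ROI counts")
  obs_names <- names(annotations)
  if (is.null(obs_names)) obs_names <- paste0("obs", seq_len(n))
  pairs <- utils::combn(n, 2L)
  res <- data.frame(observer_a = character(0), observer_b = character(0),
                    od = numeric(0), oh = numeric(0))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    rep_k <- object_metric_report(annotations[[i]], annotations[[j]])
    res <- rbind(res, data.frame(observer_a = obs_names[i],
                                 observer_b = obs_names[j],
                                 od = rep_k$od_mean, oh = rep_k$oh_mean))
  }
  structure(list(pairwise = res, od_mean = mean(res$od),
                 oh_mean = mean(res$oh), n_pairs = ncol(pairs)),
            class = "ObserverAgreementReport")
}

#' @export
print.ObserverAgreementReport <- function(x, ...) {
  cat(sprintf("<ObserverAgreementReport: %d pair(s), OD %.3f, OH %.2f px>\n",
              x$n_pairs, x$od_mean, x$oh_mean))
  invisible(x)
}
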