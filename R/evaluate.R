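#' Mean absolute error over trajectories
#'
#' Per-trajectory mean over frames, then mean over trajectories — so every
#' trajectory counts equally regardless of its length.
#'
#' @param preds,gts lists of per-frame numeric vectors (equal lengths
#'   pairwise), or single vectors.
#' @return scalar error.
#' @export
mae <- function(preds, gts) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(gts)) gts <- list(gts)
  stopifnot(length(preds) == length(gts))
  per <- mapply(function(p, g) {
    stopifnot(length(p) == length(g))
    mean(abs(p - g))
  }, preds, gts)
  mean(per)
}

#' Mean absolute log error for the diffusion coefficient
#'
#' \code{\link{mae}} applied in log10(K+1) space. Inputs already in that
#' space can be passed with \code{log_input = TRUE}.
#'
#' @param predK,gtK lists of per-frame K series.
#' @param log_input inputs are already log10(K+1).
#' @return scalar error.
#' @export
male <- function(predK, gtK, log_input = FALSE) {
  tf <- if (log_input) identity else k_to_log
  if (!is.list(predK)) predK <- list(predK)
  if (!is.list(gtK)) gtK <- list(gtK)
  mae(lapply(predK, tf), lapply(gtK, tf))
}

#' State classification metrics
#'
#' Row-normalised 4x4 confusion matrix (rows = ground truth over all frames
#' of all trajectories) and the average class accuracy (mean of the
#' diagonal over classes that occur in the ground truth; absent classes are
#' excluded, not counted as zero).
#'
#' @param pred_s,gt_s lists of per-frame integer state vectors (0..3), or
#'   single vectors.
#' @return list with \code{confusion} (row-normalised), \code{counts},
#'   \code{avg_class_accuracy}.
#' @export
state_metrics <- function(pred_s, gt_s) {
  p <- unlist(pred_s, use.names = FALSE)
  g <- unlist(gt_s, use.names = FALSE)
  stopifnot(length(p) == length(g))
  counts <- matrix(0, 4, 4, dimnames = list(gt = 0:3, pred = 0:3))
  for (k in seq_along(g)) counts[g[k] + 1L, p[k] + 1L] <-
      counts[g[k] + 1L, p[k] + 1L] + 1
  rs <- rowSums(counts)
  conf <- counts / ifelse(rs > 0, rs, NA)
  present <- rs > 0
  acc <- mean(diag(conf)[present])
  list(confusion = conf, counts = counts, avg_class_accuracy = acc)
}

#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Jonker-Volgenant style shortest-augmenting-path implementation for a
#' (possibly rectangular) cost matrix; returns, for each row, the assigned
#' column (NA when rows outnumber columns).
#'
#' @param cost numeric cost matrix.
#' @return integer vector of column assignments per row.
#' @export
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  transposed <- FALSE
  if (nr > nc) {  # algorithm needs rows <= cols
    cost <- t(cost)
    tmp <- nr; nr <- nc; nc <- tmp
    transposed <- TRUE
  }
  INF <- .Machine$double.xmax / 4
  # potentials and matching; col2row[j] = row matched to column j
  u <- numeric(nr); vpot <- numeric(nc)
  col2row <- rep(0L, nc + 1L)  # index nc+1 is the virtual start column
  for (i in seq_len(nr)) {
    j_cur <- nc + 1L
    col2row[j_cur] <- i
    minv <- rep(INF, nc)
    used <- rep(FALSE, nc + 1L)
    way <- rep(0L, nc)
    repeat {
      used[j_cur] <- TRUE
      i0 <- col2row[j_cur]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(nc)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - vpot[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j_cur
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(nc + 1L)) {
        if (used[j]) {
          if (j <= nc) vpot[j] <- vpot[j] - delta
          if (col2row[j] > 0L) u[col2row[j]] <- u[col2row[j]] + delta
        } else if (j <= nc) {
          minv[j] <- minv[j] - delta
        }
      }
      j_cur <- j1
      if (col2row[j_cur] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j_prev <- way[j_cur]
      col2row[j_cur] <- if (j_prev == nc + 1L) i else col2row[j_prev]
      j_cur <- j_prev
      if (j_cur == nc + 1L) break
    }
  }
  row2col <- rep(NA_integer_, nr)
  for (j in seq_len(nc)) if (col2row[j] > 0L) row2col[col2row[j]] <- j
  if (transposed) {
    out <- rep(NA_integer_, length(row2col))
    # row2col maps transposed rows (original cols) to transposed cols
    # (original rows); invert back
    orig <- rep(NA_integer_, nc)
    for (r in seq_len(nr)) if (!is.na(row2col[r])) orig[row2col[r]] <- r
    return(orig)
  }
  row2col
}

#' Pair predicted and true changepoints
#'
#' Minimum-total-squared-distance assignment between ground-truth and
#' predicted changepoints (Hungarian algorithm); assigned pairs closer than
#' \code{tol} frames are true positives, everything else counts as a false
#' negative (ground-truth side) or false positive (prediction side).
#'
#' @param gt,pred integer changepoint vectors.
#' @param tol pairing tolerance in frames (strict: |t_g - t_p| < tol).
#' @return list with \code{pairs} (2-column matrix gt, pred), \code{TP},
#'   \code{FN}, \code{FP}.
#' @export
pair_changepoints <- function(gt, pred, tol = 5) {
  gt <- sort(as.numeric(gt)); pred <- sort(as.numeric(pred))
  ng <- length(gt); np <- length(pred)
  if (ng == 0 || np == 0) {
    return(list(pairs = matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("gt", "pred"))),
                TP = 0L, FN = ng, FP = np))
  }
  cost <- outer(gt, pred, function(a, b) (a - b)^2)
  assign <- solve_assignment(cost)
  ok <- which(!is.na(assign))
  ok <- ok[abs(gt[ok] - pred[assign[ok]]) < tol]
  pairs <- cbind(gt = gt[ok], pred = pred[assign[ok]])
  list(pairs = pairs, TP = length(ok), FN = ng - length(ok),
       FP = np - length(ok))
}

#' Jaccard index of changepoint detection
#'
#' \eqn{J = TP / (TP + FN + FP)} over tolerance-paired changepoints. With
#' no changepoints on either side there is nothing to miss and nothing
#' spurious, so J = 1.
#'
#' @param TP,FN,FP counts (or a list as returned by
#'   \code{\link{pair_changepoints}} as first argument).
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(TP, FN = NULL, FP = NULL) {
  if (is.list(TP)) {
    FN <- TP$FN; FP <- TP$FP; TP <- TP$TP
  }
  denom <- TP + FN + FP
  if (denom == 0) return(1)
  TP / denom
}

#' RMSE of paired changepoints
#'
#' \eqn{\sqrt{\sum_{pairs} (t_g - t_p)^2 / N_{CP}}} with \eqn{N_{CP}} the
#' number of paired changepoints (the sum runs over pairs; unpaired points
#' are already captured by the Jaccard index). Undefined (NA) when nothing
#' is paired.
#'
#' @param pairs 2-column matrix (gt, pred) from
#'   \code{\link{pair_changepoints}}, or such a result list.
#' @return scalar RMSE in frames, or NA.
#' @export
cp_rmse <- function(pairs) {
  if (is.list(pairs) && !is.null(pairs$pairs)) pairs <- pairs$pairs
  if (is.null(nrow(pairs)) || nrow(pairs) == 0) return(NA_real_)
  sqrt(mean((pairs[, 1] - pairs[, 2])^2))
}

#' Score a set of predictions against ground truth
#'
#' Aggregates the pointwise and changepoint metrics over a list of tracks.
#'
#' @param tracks list of \code{sim_track} objects (ground truth).
#' @param preds list (parallel to \code{tracks}) with elements
#'   \code{alpha}, \code{logK}, \code{s} (any may be NULL) and
#'   \code{changepoints}.
#' @param cp_tol changepoint pairing tolerance in frames.
#' @return list of class \code{metrics_report}: \code{mae_alpha},
#'   \code{male_K}, state metrics, mean \code{jaccard}, mean \code{cp_rmse}
#'   (over trajectories where it is defined), and totals.
#' @export
score_predictions <- function(tracks, preds, cp_tol = 5) {
  has <- function(f) !is.null(preds[[1]][[f]])
  out <- list()
  if (has("alpha")) {
    out$mae_alpha <- mae(lapply(preds, `[[`, "alpha"),
                         lapply(tracks, `[[`, "alpha"))
  }
  if (has("logK")) {
    out$male_K <- mae(lapply(preds, `[[`, "logK"),
                      lapply(tracks, function(t) k_to_log(t$K)))
  }
  if (has("s")) {
    sm <- state_metrics(lapply(preds, `[[`, "s"),
                        lapply(tracks, `[[`, "state"))
    out$confusion <- sm$confusion
    out$avg_class_accuracy <- sm$avg_class_accuracy
  }
  if (has("changepoints") || !is.null(preds[[1]]$changepoints)) {
    js <- numeric(length(tracks)); rs <- numeric(length(tracks))
    for (i in seq_along(tracks)) {
      pr <- pair_changepoints(tracks[[i]]$changepoints,
                              preds[[i]]$changepoints, tol = cp_tol)
      js[i] <- jaccard(pr)
      rs[i] <- cp_rmse(pr)
    }
    out$jaccard <- mean(js)
    out$cp_rmse <- if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  if (!is.null(x$mae_alpha)) cat(sprintf("  MAE(alpha):  %.4f\n", x$mae_alpha))
  if (!is.null(x$male_K)) cat(sprintf("  MALE(K):     %.4f\n", x$male_K))
  if (!is.null(x$avg_class_accuracy))
    cat(sprintf("  avg class accuracy: %.3f\n", x$avg_class_accuracy))
  if (!is.null(x$jaccard)) cat(sprintf("  Jaccard:     %.3f\n", x$jaccard))
  if (!is.null(x$cp_rmse)) cat(sprintf("  CP RMSE:     %.3f\n", x$cp_rmse))
  invisible(x)
}
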