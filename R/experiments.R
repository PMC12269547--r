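#' End-to-end inference on a set of trajectories
#'
#' Runs every supplied per-variable model, smooths the outputs, enforces
#' the minimum state duration and detects merged changepoints.
#'
#' @param models named list with any of \code{alpha}, \code{K}, \code{state}
#'   (trained \code{difftrack_net} objects).
#' @param tracks list of \code{sim_track} (or any list with \code{x, y}).
#' @param params a \code{\link{seg_params}}.
#' @param batch prediction batch size.
#' @return list of predictions: \code{alpha}, \code{logK}, \code{s},
#'   per-variable \code{cp_sets} and merged \code{changepoints}.
#' @export
infer_tracks <- function(models, tracks, params = seg_params(),
                         batch = 64L) {
  pa <- if (!is.null(models$alpha))
    predict_tracks(models$alpha, tracks, batch)
  pk <- if (!is.null(models$K)) predict_tracks(models$K, tracks, batch)
  ps <- if (!is.null(models$state))
    predict_tracks(models$state, tracks, batch)
  lapply(seq_along(tracks), function(i) {
    pp <- postprocess_predictions(
      alpha_hat = if (!is.null(pa)) pa[[i]],
      logK_hat = if (!is.null(pk)) pk[[i]],
      s_hat = if (!is.null(ps)) ps[[i]]$s_hat,
      params = params)
    list(alpha = pp$alpha, logK = pp$logK, s = pp$state,
         cp_sets = pp$cp_sets, changepoints = pp$changepoints)
  })
}

#' Error as a function of trajectory length
#'
#' Bins test trajectories by length and reports the mean per-variable error
#' per bin (the losses decrease with length as more evidence accumulates).
#'
#' @param tracks ground-truth tracks.
#' @param preds predictions from \code{\link{infer_tracks}}.
#' @param breaks length-bin boundaries in frames.
#' @return data.frame with one row per bin: n, mae_alpha, male_K,
#'   class_accuracy (whichever variables are present).
#' @export
eval_by_length <- function(tracks, preds,
                           breaks = seq(20, 200, by = 30)) {
  lens <- vapply(tracks, function(t) length(t$x), integer(1))
  bin <- cut(lens, breaks = unique(c(breaks, Inf)), include.lowest = TRUE,
             right = TRUE)
  do.call(rbind, lapply(levels(bin), function(b) {
    ii <- which(bin == b)
    if (length(ii) == 0) return(NULL)
    row <- data.frame(bin = b, n = length(ii))
    if (!is.null(preds[[ii[1]]]$alpha))
      row$mae_alpha <- mae(lapply(preds[ii], `[[`, "alpha"),
                           lapply(tracks[ii], `[[`, "alpha"))
    if (!is.null(preds[[ii[1]]]$logK))
      row$male_K <- mae(lapply(preds[ii], `[[`, "logK"),
                        lapply(tracks[ii], function(t) k_to_log(t$K)))
    if (!is.null(preds[[ii[1]]]$s))
      row$class_accuracy <- state_metrics(
        lapply(preds[ii], `[[`, "s"),
        lapply(tracks[ii], `[[`, "state"))$avg_class_accuracy
    row
  }))
}

#' Changepoint scores by number of true changepoints
#'
#' @param tracks ground-truth tracks.
#' @param preds predictions from \code{\link{infer_tracks}}.
#' @param cp_tol pairing tolerance in frames.
#' @return data.frame: n_cp, n, jaccard, cp_rmse, and the pointwise errors.
#' @export
eval_by_ncp <- function(tracks, preds, cp_tol = 5) {
  ncp <- vapply(tracks, function(t) length(t$changepoints), integer(1))
  do.call(rbind, lapply(sort(unique(ncp)), function(k) {
    ii <- which(ncp == k)
    prs <- lapply(ii, function(i)
      pair_changepoints(tracks[[i]]$changepoints,
                        preds[[i]]$changepoints, tol = cp_tol))
    rmses <- vapply(prs, cp_rmse, numeric(1))
    row <- data.frame(
      n_cp = k, n = length(ii),
      jaccard = mean(vapply(prs, jaccard, numeric(1))),
      cp_rmse = if (all(is.na(rmses))) NA_real_
                else mean(rmses, na.rm = TRUE))
    if (!is.null(preds[[ii[1]]]$alpha))
      row$mae_alpha <- mae(lapply(preds[ii], `[[`, "alpha"),
                           lapply(tracks[ii], `[[`, "alpha"))
    if (!is.null(preds[[ii[1]]]$logK))
      row$male_K <- mae(lapply(preds[ii], `[[`, "logK"),
                        lapply(tracks[ii], function(t) k_to_log(t$K)))
    row
  }))
}

#' Changepoint scores for different variable subsets
#'
#' Re-merges the per-variable changepoint sets under each requested subset
#' (first element = anchor) and scores them, to compare e.g. K alone
#' against alpha+K and alpha+K+state.
#'
#' @param tracks ground-truth tracks.
#' @param preds predictions from \code{\link{infer_tracks}} (must carry
#'   \code{cp_sets}).
#' @param subsets list of character vectors over c("K","alpha","state").
#' @param dedup_window merge window in frames.
#' @param cp_tol pairing tolerance in frames.
#' @return data.frame: subset, jaccard, cp_rmse.
#' @export
eval_cp_variables <- function(tracks, preds,
                              subsets = list("K", "alpha", "state",
                                             c("K", "alpha"),
                                             c("K", "alpha", "state")),
                              dedup_window = 5L, cp_tol = 5) {
  do.call(rbind, lapply(subsets, function(vars) {
    js <- numeric(length(tracks)); rs <- numeric(length(tracks))
    for (i in seq_along(tracks)) {
      sets <- preds[[i]]$cp_sets
      vv <- vars[vars %in% names(sets)]
      merged <- if (length(vv) == 0) integer(0) else
        merge_changepoint_sets(sets[[vv[1]]], unname(sets[vv[-1]]),
                               dedup_window)
      pr <- pair_changepoints(tracks[[i]]$changepoints, merged, tol = cp_tol)
      js[i] <- jaccard(pr)
      rs[i] <- cp_rmse(pr)
    }
    data.frame(subset = paste(vars, collapse = "+"),
               jaccard = mean(js),
               cp_rmse = if (all(is.na(rs))) NA_real_
                         else mean(rs, na.rm = TRUE))
  }))
}

#' Changepoint sensitivity to the parameter difference at a changepoint
#'
#' Simulates two-segment trajectories with a single midpoint changepoint
#' (\code{\link{simulate_two_segment}}), varying either alpha (K fixed at 1)
#' or K (alpha fixed at 1) across the changepoint, and reports the mean
#' Jaccard index per difference. With zero difference the segments are
#' statistically identical and nothing is detectable, so the Jaccard index
#' is 0 against the recorded midpoint changepoint.
#'
#' @param models named model list (see \code{\link{infer_tracks}}).
#' @param deltas differences to sweep (alpha units, or a multiplier on K).
#' @param vary "alpha" or "K".
#' @param n trajectories per sweep point.
#' @param T trajectory length.
#' @param base baseline value of the varied parameter's first segment.
#' @param params a \code{\link{seg_params}}.
#' @return data.frame: delta, jaccard, cp_rmse.
#' @export
sweep_delta <- function(models, deltas, vary = c("alpha", "K"), n = 50L,
                        T = 200L, base = 1, params = seg_params()) {
  vary <- match.arg(vary)
  do.call(rbind, lapply(deltas, function(d) {
    tracks <- lapply(seq_len(n), function(i) {
      if (vary == "alpha") {
        a1 <- base
        a2 <- min(max(a1 + d, 0), 2)
        simulate_two_segment(a1, 1, a2, 1, T)
      } else {
        simulate_two_segment(1, base, 1, max(base + d, 0), T)
      }
    })
    preds <- infer_tracks(models, tracks, params)
    prs <- lapply(seq_len(n), function(i)
      pair_changepoints(tracks[[i]]$changepoints,
                        preds[[i]]$changepoints))
    rmses <- vapply(prs, cp_rmse, numeric(1))
    data.frame(delta = d,
               jaccard = mean(vapply(prs, jaccard, numeric(1))),
               cp_rmse = if (all(is.na(rmses))) NA_real_
                         else mean(rmses, na.rm = TRUE))
  }))
}

#' Error by biological model
#'
#' @param tracks ground-truth tracks (with their \code{model} field).
#' @param preds predictions from \code{\link{infer_tracks}}.
#' @return data.frame per model: n, mae_alpha, male_K, jaccard.
#' @export
eval_by_model <- function(tracks, preds) {
  mods <- vapply(tracks, `[[`, "", "model")
  do.call(rbind, lapply(sort(unique(mods)), function(m) {
    ii <- which(mods == m)
    prs <- lapply(ii, function(i)
      pair_changepoints(tracks[[i]]$changepoints,
                        preds[[i]]$changepoints))
    row <- data.frame(model = m, n = length(ii),
                      jaccard = mean(vapply(prs, jaccard, numeric(1))))
    if (!is.null(preds[[ii[1]]]$alpha))
      row$mae_alpha <- mae(lapply(preds[ii], `[[`, "alpha"),
                           lapply(tracks[ii], `[[`, "alpha"))
    if (!is.null(preds[[ii[1]]]$logK))
      row$male_K <- mae(lapply(preds[ii], `[[`, "logK"),
                        lapply(tracks[ii], function(t) k_to_log(t$K)))
    row
  }))
}

#' Run the evaluation experiment suite
#'
#' Scores a trained model set on a test set and produces, at the scale of
#' the supplied data, the standard result tables: overall metrics, error
#' versus trajectory length, changepoint scores versus the number of true
#' changepoints and versus the changepoint-variable subset, and the
#' per-biological-model breakdown.
#'
#' @param models named model list (see \code{\link{infer_tracks}}).
#' @param tracks test tracks.
#' @param params a \code{\link{seg_params}}.
#' @return list of data.frames/reports.
#' @export
experiment_suite <- function(models, tracks, params = seg_params()) {
  preds <- infer_tracks(models, tracks, params)
  list(overall = score_predictions(tracks, preds),
       by_length = eval_by_length(tracks, preds),
       by_ncp = eval_by_ncp(tracks, preds),
       by_cp_vars = eval_cp_variables(tracks, preds),
       by_model = eval_by_model(tracks, preds))
}
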