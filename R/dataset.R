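#' Default dataset recipe
#'
#' Trajectory counts per simulation tranche, mirroring the training-data
#' protocol: equal counts for the five models; a repeat with alpha
#' constrained to \[1.9, 2\] (enriching the minority directed state); and
#' single-variable-change variants of the three models with interacting
#' segments (MSM, DIM, TCM) in which changepoints occur in only one of
#' alpha or K. At \code{per_model = 4e5} the total is the full 5.2 million;
#' \code{\link{build_dataset}}'s \code{scale_factor} shrinks it for desk
#' use.
#'
#' @param per_model trajectories per model per tranche.
#' @return named list of per-model counts by tranche.
#' @export
dataset_recipe <- function(per_model = 400000) {
  models <- c("SSM", "MSM", "QTM", "TCM", "DIM")
  list(base = stats::setNames(rep(per_model, 5), models),
       alpha_constrained = stats::setNames(rep(per_model, 5), models),
       single_change = stats::setNames(rep(per_model, 3),
                                       c("MSM", "DIM", "TCM")))
}

# integer apportionment: floors plus largest fractional remainders, so the
# rounded total is hit exactly
largest_remainder <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

# simulate valid (FOV-truncated, long-enough) tracks for a config;
# parameters are redrawn on every attempt, so fast-escaping draws are
# naturally suppressed, as they are by a finite field of view. Dimer pairs
# are truncated per particle: a usable partner is kept even when the other
# particle exits too early.
sim_valid <- function(cfg, min_T = 20L, max_try = 500L) {
  for (k in seq_len(max_try)) {
    tr <- simulate_track(cfg)
    trs <- if (inherits(tr, "sim_track")) list(tr) else tr
    kept <- Filter(Negate(is.null),
                   lapply(trs, apply_fov, fov = cfg$fov, min_T = min_T))
    if (length(kept) >= 1) return(kept)
  }
  stop("could not simulate a trajectory that stays in the field of view")
}

#' Build a simulated dataset
#'
#' Simulates trajectories per the recipe (scaled by \code{scale_factor},
#' apportioned by largest remainder so the scaled total is exact), with
#' trajectory lengths drawn uniformly from \code{T_range} and a random
#' 60:20:20 train/val/test split. Deterministic given \code{seed}.
#'
#' Tranches: \code{base} uses the full alpha range; \code{alpha_constrained}
#' restricts alpha to \[1.9, 2\]; \code{single_change} alternates between
#' fixing K (alpha-only changes) and fixing alpha (K-only changes) across
#' trajectories.
#'
#' @param recipe see \code{\link{dataset_recipe}}.
#' @param scale_factor multiplier on the recipe counts.
#' @param seed integer seed.
#' @param T_range trajectory length range in frames.
#' @param fov field-of-view side length in pixels.
#' @return list of class \code{difftrack_dataset}: \code{tracks},
#'   \code{split} (factor train/val/test), \code{meta}.
#' @export
build_dataset <- function(recipe = dataset_recipe(), scale_factor = 1,
                          seed = 1L, T_range = c(20L, 200L), fov = 128) {
  set.seed(seed)
  # apportion jointly over every recipe cell so the scaled total is exact
  flat <- unlist(recipe) * scale_factor
  alloc <- largest_remainder(flat)
  counts <- utils::relist(alloc, recipe)
  counts <- lapply(counts, function(x) stats::setNames(as.integer(x),
                                                       names(x)))
  tracks <- list()
  origin <- character(0)
  rand_T <- function() sample(seq.int(T_range[1], T_range[2]), 1)
  add <- function(trs, tag) {
    tracks[seq_along(trs) + length(tracks)] <<- trs
    origin <<- c(origin, rep(tag, length(trs)))
  }
  for (tranche in names(counts)) {
    for (model in names(counts[[tranche]])) {
      n_left <- counts[[tranche]][[model]]
      i <- 0L
      while (n_left > 0) {
        i <- i + 1L
        ar <- if (tranche == "alpha_constrained") c(1.9, 2) else c(0, 2)
        # a fixed parameter is part of the redrawn configuration: retrying
        # the field-of-view cut must resample it too, or a fast-escaping
        # fixed K could never produce a valid trajectory
        trs <- NULL
        repeat {
          fx_a <- NULL; fx_K <- NULL
          if (tranche == "single_change") {
            if (i %% 2L == 1L) fx_K <- sample_K(c(1e-12, 1e6))
            else fx_a <- if (model == "TCM")
              sample_alpha_confined(ar) else sample_alpha(ar)
          }
          cfg <- sim_config(model, T = rand_T(), fov = fov,
                            alpha_range = ar,
                            fixed_alpha = fx_a, fixed_K = fx_K)
          trs <- tryCatch(sim_valid(cfg, max_try = 25L),
                          error = function(e) NULL)
          if (!is.null(trs)) break
        }
        trs <- trs[seq_len(min(length(trs), n_left))]
        add(trs, paste(tranche, model, sep = "."))
        n_left <- n_left - length(trs)
      }
    }
  }
  n <- length(tracks)
  split_n <- largest_remainder(n * c(0.6, 0.2, 0.2), n)
  split <- factor(sample(rep(c("train", "val", "test"), split_n)),
                  levels = c("train", "val", "test"))
  structure(list(tracks = tracks, split = split, origin = origin,
                 meta = list(seed = seed, scale_factor = scale_factor,
                             counts = counts, T_range = T_range, fov = fov)),
            class = "difftrack_dataset")
}

#' @export
print.difftrack_dataset <- function(x, ...) {
  cat(sprintf("<difftrack_dataset> %d tracks (%s)\n", length(x$tracks),
              paste(sprintf("%s %d", levels(x$split), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a dataset by split
#'
#' @param ds a \code{difftrack_dataset}.
#' @param which "train", "val" or "test".
#' @return list of \code{sim_track}.
#' @export
dataset_split <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  ds$tracks[ds$split == which]
}

# --- CSV / YAML interchange ----------------------------------------------

#' Write a dataset to disk
#'
#' Plain-text interchange: \code{trajectories.csv}
#' (\code{traj_id,frame,x,y}; frames 0-based, pixels), \code{labels.csv}
#' (\code{traj_id,frame,alpha,K,state}), \code{changepoints.csv}
#' (\code{traj_id,cp_frame}) and a \code{manifest.yaml} recording files,
#' split membership, seed and recipe counts.
#'
#' @param ds a \code{difftrack_dataset}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ds$tracks)
  ids <- sprintf("t%05d", seq_len(n))
  lens <- vapply(ds$tracks, function(t) length(t$x), integer(1))
  traj <- data.frame(
    traj_id = rep(ids, lens),
    frame = unlist(lapply(lens, function(l) 0:(l - 1L))),
    x = unlist(lapply(ds$tracks, `[[`, "x")),
    y = unlist(lapply(ds$tracks, `[[`, "y")))
  labs <- data.frame(
    traj_id = traj$traj_id, frame = traj$frame,
    alpha = unlist(lapply(ds$tracks, `[[`, "alpha")),
    K = unlist(lapply(ds$tracks, `[[`, "K")),
    state = unlist(lapply(ds$tracks, `[[`, "state")))
  ncp <- vapply(ds$tracks, function(t) length(t$changepoints), integer(1))
  cps <- data.frame(
    traj_id = rep(ids, ncp),
    cp_frame = unlist(lapply(ds$tracks, `[[`, "changepoints")))
  utils::write.csv(traj, file.path(dir, "trajectories.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(labs, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cps, file.path(dir, "changepoints.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    files = list(trajectories = "trajectories.csv",
                 labels = "labels.csv",
                 changepoints = "changepoints.csv"),
    split = split(ids, ds$split),
    model = lapply(split(vapply(ds$tracks, `[[`, "", "model"),
                         factor(ids, levels = ids)), identity),
    meta = ds$meta),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset from disk
#'
#' Inverse of \code{\link{write_dataset}}; validates the schema and
#' reassembles \code{sim_track} objects with their split membership.
#'
#' @param dir dataset directory containing a \code{manifest.yaml}.
#' @return a \code{difftrack_dataset}.
#' @export
read_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  traj <- utils::read.csv(file.path(dir, man$files$trajectories))
  need <- c("traj_id", "frame", "x", "y")
  if (!all(need %in% names(traj)))
    stop("trajectories.csv must have columns ", paste(need, collapse = ","))
  if (any(!is.finite(traj$x)) || any(!is.finite(traj$y)))
    stop("non-finite coordinates in trajectories.csv")
  labs <- utils::read.csv(file.path(dir, man$files$labels))
  cps <- utils::read.csv(file.path(dir, man$files$changepoints))
  ids <- unique(traj$traj_id)
  model_of <- unlist(man$model)
  tr_by <- split(traj[c("frame", "x", "y")], factor(traj$traj_id, ids))
  lab_by <- split(labs[c("alpha", "K", "state")], factor(labs$traj_id, ids))
  cp_by <- split(cps$cp_frame, factor(cps$traj_id, ids))
  tracks <- lapply(ids, function(id) {
    tt <- tr_by[[id]]
    ll <- lab_by[[id]]
    ord <- order(tt$frame)
    make_sim_track(tt$x[ord], tt$y[ord], ll$alpha[ord], ll$K[ord],
                   ll$state[ord],
                   model = if (id %in% names(model_of)) model_of[[id]]
                           else NA_character_,
                   changepoints = sort(cp_by[[id]]))
  })
  split_vec <- rep(NA_character_, length(ids))
  for (s in names(man$split)) split_vec[ids %in% man$split[[s]]] <- s
  structure(list(tracks = tracks,
                 split = factor(split_vec,
                                levels = c("train", "val", "test")),
                 origin = NULL, meta = man$meta),
            class = "difftrack_dataset")
}

#' Write per-frame predictions and changepoints
#'
#' @param preds list of prediction lists (fields \code{alpha}, \code{logK},
#'   \code{s}, \code{changepoints}; any may be NULL).
#' @param ids trajectory identifiers.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_predictions <- function(preds, ids, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(preds), function(i) {
    p <- preds[[i]]
    T <- length(p$alpha %||% p$logK %||% p$s)
    data.frame(traj_id = ids[i], frame = 0:(T - 1L),
               alpha_hat = if (is.null(p$alpha)) NA else p$alpha,
               logK_hat = if (is.null(p$logK)) NA else p$logK,
               state_hat = if (is.null(p$s)) NA else p$s)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  ncp <- vapply(preds, function(p) length(p$changepoints), integer(1))
  utils::write.csv(
    data.frame(traj_id = rep(ids, ncp),
               cp_frame = unlist(lapply(preds, `[[`, "changepoints"))),
    file.path(dir, "changepoints.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
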