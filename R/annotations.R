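#' Observer annotation table
#'
#' Raw keypress logs: one row per press with `observer_id`, `run_id` and
#' `press_time_s`. The `rt_corrected` attribute records whether reaction-time
#' correction has been applied.
#'
#' @param observer_id,run_id character/factor identifiers (recycled).
#' @param press_time_s numeric press times in seconds.
#' @param rt_corrected logical flag.
#' @return data frame of class `observer_annotations`.
#' @export
observer_annotations <- function(observer_id, run_id, press_time_s,
                                 rt_corrected = FALSE) {
  if (any(press_time_s < 0)) stop("press times must be >= 0")
  df <- data.frame(observer_id = as.character(observer_id),
                   run_id = as.character(run_id),
                   press_time_s = as.numeric(press_time_s))
  df <- df[order(df$observer_id, df$run_id, df$press_time_s), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, rt_corrected = rt_corrected,
            class = c("observer_annotations", "data.frame"))
}

#' Read / write observer annotation TSV files
#'
#' @param path file path; columns `observer_id`, `run_id`, `press_time_s`.
#' @param rt_corrected whether the stored times are already RT-corrected.
#' @return an `observer_annotations` table.
#' @export
read_annotations <- function(path, rt_corrected = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  observer_annotations(df$observer_id, df$run_id, df$press_time_s,
                       rt_corrected = rt_corrected)
}

#' @rdname read_annotations
#' @param annotations an `observer_annotations` table to write.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subtract the observers' reaction time from logged presses
#'
#' Keypresses lag the perceived boundary; a fixed reaction time (0.9 s by
#' default, estimated from prior testing) is subtracted from every press,
#' clamping at 0. Applying the correction twice is an error.
#'
#' @param annotations an `observer_annotations` table.
#' @param rt reaction time in seconds (>= 0).
#' @return the corrected table, `rt_corrected` set.
#' @export
correct_rt <- function(annotations, rt = 0.9) {
  stopifnot(inherits(annotations, "observer_annotations"))
  stopifnot_scalar(rt, "rt", nonneg = TRUE)
  if (isTRUE(attr(annotations, "rt_corrected")))
    stop("annotations are already RT-corrected")
  annotations$press_time_s <- pmax(0, annotations$press_time_s - rt)
  attr(annotations, "rt_corrected") <- TRUE
  annotations
}

# cluster presses of one run: single-linkage chaining in time order --
# a press joins the current cluster while within `radius` of the previous
# member. One observer contributing several presses to a cluster counts once,
# with their times averaged first.
cluster_presses <- function(obs, times, radius) {
  o <- order(times)
  times <- times[o]; obs <- obs[o]
  cl <- cumsum(c(1, diff(times) > radius))
  out <- lapply(split(seq_along(times), cl), function(idx) {
    per_obs <- tapply(times[idx], obs[idx], mean)
    list(time = mean(per_obs), n_observers = length(per_obs),
         member_times = as.numeric(per_obs))
  })
  unname(out)
}

#' Merge observers' presses into consensus boundaries
#'
#' Two-pass merge. Pass 1: presses from different observers within 1 TR of
#' one another (single-linkage chaining in time order) are treated as a single
#' boundary whose time is the mean of the contributing observers' times.
#' Pass 2 (run once, not to convergence, to avoid long merge chains):
#' consecutive pass-1 boundaries that are each endorsed by at least two
#' observers and lie < 2 TRs apart are replaced by one boundary whose time is
#' the mean over all original observers' times and whose observer count is the
#' sum of the two.
#'
#' @param annotations an RT-corrected `observer_annotations` table.
#' @param tr repetition time in seconds (the merge radius).
#' @return consensus-boundary data frame: `run_id`, `time`, `n_observers`,
#'   `salience_bin` (NA until [bin_salience()]), plus a `member_times`
#'   list-column holding each contributing observer's (averaged) press time.
#' @export
merge_boundaries <- function(annotations, tr) {
  stopifnot(inherits(annotations, "observer_annotations"))
  stopifnot_scalar(tr, "tr", positive = TRUE)
  if (!isTRUE(attr(annotations, "rt_corrected")))
    stop("annotations must be RT-corrected first (see correct_rt)")
  if (nrow(annotations) == 0L)
    return(empty_boundaries())

  res <- list()
  for (run in unique(annotations$run_id)) {
    a <- annotations[annotations$run_id == run, , drop = FALSE]
    cl <- cluster_presses(a$observer_id, a$press_time_s, radius = tr)
    # pass 2: merge adjacent pairs (both n >= 2, gap < 2 TR), left to right,
    # each boundary participating in at most one merge
    merged <- list(); i <- 1L
    while (i <= length(cl)) {
      if (i < length(cl) &&
          cl[[i]]$n_observers >= 2L && cl[[i + 1L]]$n_observers >= 2L &&
          (cl[[i + 1L]]$time - cl[[i]]$time) < 2 * tr) {
        mt <- c(cl[[i]]$member_times, cl[[i + 1L]]$member_times)
        merged[[length(merged) + 1L]] <-
          list(time = mean(mt),
               n_observers = cl[[i]]$n_observers + cl[[i + 1L]]$n_observers,
               member_times = mt)
        i <- i + 2L
      } else {
        merged[[length(merged) + 1L]] <- cl[[i]]
        i <- i + 1L
      }
    }
    res[[run]] <- data.frame(
      run_id = run,
      time = vapply(merged, `[[`, numeric(1), "time"),
      n_observers = vapply(merged, `[[`, integer(1), "n_observers"),
      salience_bin = NA_character_)
    res[[run]]$member_times <- I(lapply(merged, `[[`, "member_times"))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$run_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_boundaries <- function() {
  df <- data.frame(run_id = character(), time = numeric(),
                   n_observers = integer(), salience_bin = character())
  df$member_times <- I(list())
  df
}

#' Remove boundaries near the end of the run
#'
#' Boundaries within `margin` seconds of the end of the run cannot be
#' properly estimated (the response extends past the acquisition) and are
#' removed.
#'
#' @param boundaries consensus-boundary data frame.
#' @param run_duration run duration in seconds (scalar, or named vector per
#'   run id).
#' @param margin seconds (default 10).
#' @return the filtered data frame.
#' @export
drop_run_end <- function(boundaries, run_duration, margin = 10) {
  if (nrow(boundaries) == 0L) return(boundaries)
  dur <- if (length(run_duration) > 1L)
    run_duration[boundaries$run_id] else rep(run_duration, nrow(boundaries))
  keep <- boundaries$time <= dur - margin
  out <- boundaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose the observer-count threshold for boundary inclusion
#'
#' The "true" number of boundaries is estimated as the mean number of presses
#' per observer; the threshold is the observer count k whose number of
#' boundaries with `n_observers >= k` comes closest to that estimate. Ties
#' are broken toward the lower (more inclusive) k.
#'
#' @param boundaries consensus-boundary data frame.
#' @param annotations the `observer_annotations` the boundaries came from.
#' @return the selected threshold (integer).
#' @export
select_threshold <- function(boundaries, annotations) {
  stopifnot(nrow(boundaries) > 0L)
  n_obs <- length(unique(annotations$observer_id))
  target <- nrow(annotations) / n_obs
  ks <- seq_len(max(boundaries$n_observers))
  counts <- vapply(ks, function(k) sum(boundaries$n_observers >= k), integer(1))
  ks[which.min(abs(counts - target))]
}

#' Apply an observer-count threshold
#'
#' @param boundaries consensus-boundary data frame.
#' @param threshold minimum `n_observers` for inclusion.
#' @return the filtered data frame.
#' @export
apply_threshold <- function(boundaries, threshold) {
  out <- boundaries[boundaries$n_observers >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin boundaries into three salience levels
#'
#' Partitions the sorted distinct observer counts into three contiguous
#' ranges so that each level holds approximately the same number of
#' boundaries: the partition minimises the sum of squared deviations of the
#' bin counts from N/3, with ties broken by minimising the difference between
#' the low- and high-bin counts. With fewer than three distinct counts the
#' binning is degenerate and flagged.
#'
#' @param boundaries consensus-boundary data frame.
#' @return the data frame with `salience_bin` set to `"low"`/`"med"`/`"high"`
#'   and attributes `bin_edges` (list of value ranges) and `degenerate`.
#' @export
bin_salience <- function(boundaries) {
  n <- nrow(boundaries)
  if (n == 0L) return(boundaries)
  vals <- sort(unique(boundaries$n_observers))
  labs <- c("low", "med", "high")
  if (length(vals) < 3L) {
    bin_of <- stats::setNames(labs[seq_along(vals)], vals)
    boundaries$salience_bin <- unname(bin_of[as.character(boundaries$n_observers)])
    attr(boundaries, "degenerate") <- TRUE
    attr(boundaries, "bin_edges") <- lapply(vals, function(v) c(v, v))
    return(boundaries)
  }
  tab <- table(factor(boundaries$n_observers, levels = vals))
  best <- NULL
  for (i in seq_len(length(vals) - 2L)) {
    for (j in seq(i + 1L, length(vals) - 1L)) {
      c1 <- sum(tab[seq_len(i)])
      c2 <- sum(tab[seq(i + 1L, j)])
      c3 <- sum(tab[seq(j + 1L, length(vals))])
      sse <- sum((c(c1, c2, c3) - n / 3)^2)
      tie <- abs(c1 - c3)
      if (is.null(best) || sse < best$sse - 1e-12 ||
          (abs(sse - best$sse) <= 1e-12 && tie < best$tie)) {
        best <- list(i = i, j = j, sse = sse, tie = tie)
      }
    }
  }
  cuts <- c(vals[best$i], vals[best$j])
  bin <- ifelse(boundaries$n_observers <= cuts[1], "low",
                ifelse(boundaries$n_observers <= cuts[2], "med", "high"))
  boundaries$salience_bin <- bin
  attr(boundaries, "degenerate") <- FALSE
  attr(boundaries, "bin_edges") <- list(
    low = c(vals[1], cuts[1]),
    med = c(vals[best$i + 1L], cuts[2]),
    high = c(vals[best$j + 1L], vals[length(vals)]))
  boundaries
}

#' Full consensus-boundary chain
#'
#' Convenience wrapper: RT correction (unless already applied), two-pass
#' merging, run-end removal, threshold selection and application, and
#' salience binning.
#'
#' @param annotations an `observer_annotations` table.
#' @param tr repetition time in seconds.
#' @param rt reaction time to subtract (ignored when already corrected).
#' @param run_duration run duration(s) in seconds, or `NULL` to skip run-end
#'   removal.
#' @param margin run-end margin in seconds.
#' @param threshold observer-count threshold; `NULL` selects it from the data.
#' @return consensus-boundary data frame with attribute `threshold`.
#' @export
consensus_boundaries <- function(annotations, tr, rt = 0.9,
                                 run_duration = NULL, margin = 10,
                                 threshold = NULL) {
  if (!isTRUE(attr(annotations, "rt_corrected")))
    annotations <- correct_rt(annotations, rt)
  b <- merge_boundaries(annotations, tr)
  if (!is.null(run_duration)) b <- drop_run_end(b, run_duration, margin)
  if (nrow(b) == 0L) return(b)
  if (is.null(threshold)) threshold <- select_threshold(b, annotations)
  b <- apply_threshold(b, threshold)
  if (nrow(b)) b <- bin_salience(b)
  attr(b, "threshold") <- threshold
  b
}

#' Compare the consensus boundaries of two observer groups
#'
#' Runs the full consensus procedure separately for each observer group and
#' counts matching boundaries (greedy one-to-one, within 1 TR). The count is
#' referred to random divisions of the pooled observers into two groups of
#' the same sizes; the reported `p_lower` is the fraction of random splits
#' yielding a lower match than observed (a value near 0.5 indicates the true
#' grouping is unremarkable).
#'
#' @param annotations_a,annotations_b `observer_annotations` for the two
#'   groups (RT-corrected).
#' @param tr repetition time in seconds.
#' @param n_perm number of random splits.
#' @param run_duration,margin passed to [consensus_boundaries()].
#' @param seed optional integer seed.
#' @return list with `match` (observed count), `p_lower`, `null` (match
#'   counts under random splits) and the two boundary sets.
#' @export
compare_observer_groups <- function(annotations_a, annotations_b, tr,
                                    n_perm = 1000, run_duration = NULL,
                                    margin = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  count_matches <- function(ba, bb) {
    m <- 0L
    for (run in union(ba$run_id, bb$run_id)) {
      m <- m + nrow(greedy_match(ba$time[ba$run_id == run],
                                 bb$time[bb$run_id == run], window = tr))
    }
    m
  }
  consensus_of <- function(ann)
    consensus_boundaries(ann, tr, run_duration = run_duration, margin = margin)

  ba <- consensus_of(annotations_a)
  bb <- consensus_of(annotations_b)
  observed <- count_matches(ba, bb)

  # pool observers under disambiguated ids, then split at random
  aa <- as.data.frame(annotations_a); aa$observer_id <- paste0("A.", aa$observer_id)
  ab <- as.data.frame(annotations_b); ab$observer_id <- paste0("B.", ab$observer_id)
  pool <- rbind(aa, ab)
  ids <- unique(pool$observer_id)
  n_a <- length(unique(aa$observer_id))
  null <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    ga <- sample(ids, n_a)
    pa <- pool[pool$observer_id %in% ga, , drop = FALSE]
    pb <- pool[!pool$observer_id %in% ga, , drop = FALSE]
    ann_a <- structure(pa, rt_corrected = TRUE,
                       class = c("observer_annotations", "data.frame"))
    ann_b <- structure(pb, rt_corrected = TRUE,
                       class = c("observer_annotations", "data.frame"))
    null[i] <- count_matches(consensus_of(ann_a), consensus_of(ann_b))
  }
  list(match = observed, p_lower = mean(null < observed), null = null,
       boundaries_a = ba, boundaries_b = bb)
}

#' Write consensus boundaries to TSV
#'
#' @param boundaries consensus-boundary data frame.
#' @param path output file path.
#' @export
write_boundaries <- function(boundaries, path) {
  df <- boundaries[, c("run_id", "time", "n_observers", "salience_bin")]
  names(df)[2] <- "time_s"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
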