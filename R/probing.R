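#' In-line probing lane profile
#'
#' One lane of quantified band intensities: a sequence id, a condition (K
#' for KCl, Li for LiCl), a replicate index and a per-position intensity
#' vector over a contiguous 1..L range.
#'
#' @param seq_id sequence identifier.
#' @param condition "K" or "Li".
#' @param replicate replicate index (integer, >= 1).
#' @param intensities non-negative numeric vector; position i is the i-th
#'   element (or, if named, names must be 1..L in order).
#' @return object of class `lane_profile`.
#' @export
lane_profile <- function(seq_id, condition = c("K", "Li"), replicate,
                         intensities) {
  condition <- match.arg(condition)
  intensities <- as.numeric(intensities)
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(seq_id = seq_id, condition = condition,
         replicate = as.integer(replicate), intensities = intensities),
    class = "lane_profile"
  )
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> %s %s rep %d (%d positions)\n", x$seq_id,
              x$condition, x$replicate, length(x$intensities)))
  invisible(x)
}

#' Normalize a lane profile
#'
#' `mode = "none"` is the identity (lanes loaded at equal counts need no
#' in-silico rescaling); `mode = "total"` scales the lane so intensities
#' sum to 1, the in-silico analogue of loading equal amounts per
#' condition. Total normalization is idempotent.
#'
#' @param profile a [lane_profile()].
#' @param mode "none" or "total".
#' @return normalized [lane_profile()].
#' @export
normalize_lane <- function(profile, mode = c("none", "total")) {
  mode <- match.arg(mode)
  if (mode == "none") return(profile)
  tot <- sum(profile$intensities)
  if (tot <= 0) stop("cannot total-normalize an all-zero lane", call. = FALSE)
  profile$intensities <- profile$intensities / tot
  profile
}

#' Per-position K+/Li+ cleavage ratio profile
#'
#' Pairs K and Li lanes by replicate index and computes, per position, the
#' per-replicate ratio K/Li, the mean and standard deviation across
#' replicates, and the G4-formation call: the mean ratio must strictly
#' exceed the threshold (default 2; a mean of exactly 2 is not called).
#' A zero Li intensity makes that replicate's ratio undefined at that
#' position; the position is flagged and the undefined ratio excluded from
#' the mean rather than propagated as infinity. The SD is reported only
#' with two or more usable replicates.
#'
#' @param k_lanes,li_lanes lists of [lane_profile()]s (or single profiles)
#'   for the K and Li conditions; replicate indices must match pairwise.
#' @param threshold call threshold on the mean ratio (strict >; default 2).
#' @return object of class `probing_result`: list with `table` (data.frame
#'   position, mean_ratio, sd_ratio, n_replicates, flagged, call),
#'   `ratios` (replicate x position matrix), `threshold`, `seq_id`.
#' @export
ratio_profile <- function(k_lanes, li_lanes, threshold = 2) {
  if (inherits(k_lanes, "lane_profile")) k_lanes <- list(k_lanes)
  if (inherits(li_lanes, "lane_profile")) li_lanes <- list(li_lanes)
  if (length(k_lanes) != length(li_lanes)) {
    stop("unpaired replicates: K and Li lane counts differ", call. = FALSE)
  }
  k_lanes <- k_lanes[order(vapply(k_lanes, `[[`, 0L, "replicate"))]
  li_lanes <- li_lanes[order(vapply(li_lanes, `[[`, 0L, "replicate"))]
  reps_k <- vapply(k_lanes, `[[`, 0L, "replicate")
  reps_li <- vapply(li_lanes, `[[`, 0L, "replicate")
  if (!identical(reps_k, reps_li)) {
    stop("unpaired replicates: K and Li replicate indices differ",
         call. = FALSE)
  }
  lens <- vapply(c(k_lanes, li_lanes), function(p) length(p$intensities), 0L)
  if (length(unique(lens)) != 1L) {
    stop("position ranges differ between lanes", call. = FALSE)
  }
  L <- lens[1L]
  ratios <- t(vapply(seq_along(k_lanes), function(i) {
    k <- k_lanes[[i]]$intensities
    li <- li_lanes[[i]]$intensities
    ifelse(li > 0, k / li, NA_real_)
  }, numeric(L)))
  mean_ratio <- apply(ratios, 2L, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  n_ok <- apply(ratios, 2L, function(x) sum(!is.na(x)))
  sd_ratio <- apply(ratios, 2L, function(x) {
    if (sum(!is.na(x)) >= 2L) sd(x, na.rm = TRUE) else NA_real_
  })
  structure(
    list(table = data.frame(
           position = seq_len(L),
           mean_ratio = mean_ratio,
           sd_ratio = sd_ratio,
           n_replicates = n_ok,
           flagged = n_ok < length(k_lanes),
           call = !is.na(mean_ratio) & mean_ratio > threshold
         ),
         ratios = ratios, threshold = threshold,
         seq_id = k_lanes[[1L]]$seq_id),
    class = "probing_result"
  )
}

#' @export
print.probing_result <- function(x, ...) {
  cat(sprintf("<probing_result> %s: %d positions, %d called (mean K+/Li+ > %g)\n",
              x$seq_id, nrow(x$table), sum(x$table$call), x$threshold))
  if (!is.null(x$region_call)) {
    cat(sprintf("  region call: %s (%d supporting loop position(s))\n",
                x$region_call, length(x$supporting_positions)))
  }
  invisible(x)
}

#' Region-level G4-formation call over predicted loop positions
#'
#' The per-band twofold call is aggregated over the loop positions a
#' scanner prediction expects to bulge out: the region is called formed
#' when at least `min_support` predicted-loop positions are individually
#' called. Supporting positions are always recorded so stricter rules can
#' be applied downstream.
#'
#' @param result a [ratio_profile()] result.
#' @param predicted_loops integer positions (e.g.
#'   [locus_loop_positions()]), within the profiled range.
#' @param min_support minimum individually-called loop positions (default 1).
#' @return the `probing_result` with `region_call`,
#'   `supporting_positions`, `predicted_loops` and `min_support` added.
#' @export
call_region <- function(result, predicted_loops, min_support = 1L) {
  L <- nrow(result$table)
  predicted_loops <- as.integer(predicted_loops)
  if (length(predicted_loops) > 0 &&
      (min(predicted_loops) < 1L || max(predicted_loops) > L)) {
    stop(sprintf("predicted loop positions outside profiled range 1..%d", L),
         call. = FALSE)
  }
  called <- result$table$position[result$table$call]
  support <- intersect(predicted_loops, called)
  result$predicted_loops <- predicted_loops
  result$supporting_positions <- support
  result$min_support <- as.integer(min_support)
  result$region_call <- length(support) >= min_support
  result
}

#' Read an in-line probing intensity table
#'
#' TSV with columns seq_id, position, condition (K|Li), replicate,
#' intensity. Positions of each lane must form a contiguous 1..L range.
#'
#' @param path TSV path.
#' @return named list (by seq_id) of lists with elements `k_lanes` and
#'   `li_lanes`.
#' @export
read_probing_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("seq_id", "position", "condition", "replicate", "intensity")
  if (!all(need %in% names(df))) {
    stop(sprintf("probing TSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!all(df$condition %in% c("K", "Li"))) {
    stop("condition column must be K or Li", call. = FALSE)
  }
  lapply(split(df, df$seq_id), function(d) {
    lanes <- lapply(split(d, interaction(d$condition, d$replicate, drop = TRUE)),
                    function(lane) {
      lane <- lane[order(lane$position), ]
      if (!identical(as.integer(lane$position), seq_len(nrow(lane)))) {
        stop(sprintf("positions of %s %s rep %d are not contiguous 1..L",
                     lane$seq_id[1], lane$condition[1], lane$replicate[1]),
             call. = FALSE)
      }
      lane_profile(lane$seq_id[1], lane$condition[1], lane$replicate[1],
                   lane$intensity)
    })
    cond <- vapply(lanes, `[[`, "", "condition")
    list(k_lanes = unname(lanes[cond == "K"]),
         li_lanes = unname(lanes[cond == "Li"]))
  })
}

#' Write lane profiles as a probing TSV
#'
#' @param lanes list of [lane_profile()]s.
#' @param path output path.
#' @param provenance optional character vector of `#` comment lines.
#' @return invisibly, `path`.
#' @export
write_probing_tsv <- function(lanes, path, provenance = NULL) {
  rows <- do.call(rbind, lapply(lanes, function(p) {
    data.frame(seq_id = p$seq_id,
               position = seq_along(p$intensities),
               condition = p$condition, replicate = p$replicate,
               intensity = p$intensities, stringsAsFactors = FALSE)
  }))
  write_results_tsv(rows, path, provenance = provenance)
}
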