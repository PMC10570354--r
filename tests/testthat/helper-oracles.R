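# Independent oracles used to check the package's algorithms on small
# instances. These deliberately re-derive results by brute force or closed
# form rather than calling the implementation under test.

# maximum-cardinality matching between truth and detected spikes with
# |t - d| <= bin, by exhaustive recursion (fine for <= 12 spikes)
bf_max_matching <- function(truth, det, bin) {
  if (length(truth) == 0 || length(det) == 0) return(0L)
  best <- bf_max_matching(truth[-1], det, bin)
  for (j in seq_along(det)) {
    if (abs(det[j] - truth[1]) <= bin)
      best <- max(best, 1L + bf_max_matching(truth[-1], det[-j], bin))
  }
  best
}

# independent re-derivation of the batch-prefix SNR selection: rank pixels by
# correlation with the mask-summed trace, evaluate every batch prefix, return
# the selected pixel set (ties toward fewer batches)
bf_best_prefix <- function(movie_detr, initial, protocol, batch) {
  flat <- matrix(movie_detr$frames, nrow = dim(movie_detr$frames)[1])
  idx <- which(mask_grid(initial))
  overall <- rowSums(flat[, idx, drop = FALSE])
  ord <- idx[order(stats::cor(flat[, idx, drop = FALSE], overall),
                   decreasing = TRUE)]
  tt <- (seq_len(nrow(flat)) - 1) / movie_detr$rate
  ev <- protocol$events
  in_event <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(ev)))
    in_event[tt >= ev$onset[i] & tt < ev$onset[i] + ev$duration[i] + 0.5] <- TRUE
  snr_of <- function(pix) {
    s <- rowSums(flat[, pix, drop = FALSE])
    base <- s[!in_event]
    max(abs(s[in_event] - mean(base))) / stats::sd(base)
  }
  nb <- ceiling(length(ord) / batch)
  snrs <- vapply(seq_len(nb), function(b)
    snr_of(ord[seq_len(min(b * batch, length(ord)))]), numeric(1))
  ord[seq_len(min(which.max(snrs) * batch, length(ord)))]
}

# small uniform-grid trace builder for closed-form cases
make_trace <- function(values, rate, ...) trace(values, rate, ...)
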