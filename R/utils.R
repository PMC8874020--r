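# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed
#'
#' Mixes a base seed with integer tags (subject, day, modality index, ...)
#' into a new seed below 2^31, so that every stochastic unit of the generator
#' draws from its own stream and output is invariant to evaluation order.
#'
#' @param seed base integer seed.
#' @param ... further integer tags.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + as.numeric(t) + 1) %% 2147483647
  as.integer(h)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# Region of a 10-20 channel name.  The default montage mapping is fixed
# (C3/C4 carry the central-parietal contrast); other names fall back to a
# prefix rule so 32-channel montages (CP1, PO3, ...) group sensibly.
eeg_channel_regions <- function(ch) {
  r <- unname(EEG_REGIONS[ch])
  unknown <- is.na(r)
  if (any(unknown)) {
    nm <- ch[unknown]
    r[unknown] <- ifelse(grepl("^CP", nm), "CentralParietal",
                  ifelse(grepl("^P", nm), "Parietal",
                  ifelse(grepl("^C", nm), "Central", "Other")))
  }
  names(r) <- ch
  r
}

# channels x bands matrix of pain-effect directions: parietal +1 in every
# band, central-parietal -1 in alpha/beta/gamma, elsewhere 0.
eeg_effect_directions <- function(ch) {
  regions <- eeg_channel_regions(ch)
  d <- sapply(seq_len(nrow(EEG_BANDS)), function(bi)
    ifelse(regions == "Parietal", 1,
           ifelse(regions == "CentralParietal" &
                    EEG_BANDS$name[bi] %in% c("alpha", "beta", "gamma"),
                  -1, 0)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  dimnames(d) <- list(ch, EEG_BANDS$name)
  d
}

#' Simple peak detection with a minimum inter-peak distance
#'
#' Local maxima above `height` are kept greedily from the highest down,
#' discarding candidates closer than `min_dist_s` to an accepted peak.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param min_dist_s minimum separation between accepted peaks, seconds.
#' @param height absolute height threshold; default `mean(x) + 0.5 * sd(x)`.
#' @return integer vector of peak indices, in increasing order.
#' @keywords internal
find_peaks <- function(x, fs, min_dist_s, height = NULL) {
  n <- length(x)
  if (n < 3) return(integer(0))
  if (is.null(height)) height <- mean(x) + 0.5 * sd(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > height]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- min_dist_s * fs
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}
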