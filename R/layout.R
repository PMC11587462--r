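#' Default electrode layout
#'
#' A BioSemi-style two-bank (A/B) layout of up to 32 electrodes placed on the
#' unit disc (top view of the scalp, nose pointing towards positive y).
#' Electrodes sit on concentric rings; the name `B16` is always attached to
#' the most right-posterior electrode so that the default effect topography
#' (a right-posterior bump, where pattern-glare discomfort effects
#' concentrate) has a stable anchor across layout sizes.
#'
#' @param n_channels number of electrodes (4 to 32).
#' @return a data.frame with columns `channel`, `x`, `y` (unit-disc
#'   coordinates).
#' @export
default_layout <- function(n_channels = 32) {
  if (n_channels < 2 || n_channels > 32) {
    stop("n_channels must be between 2 and 32")
  }
  ring_n <- c(1, 7, 10, 14)
  ring_r <- c(0, 0.33, 0.66, 0.95)
  xs <- numeric(0)
  ys <- numeric(0)
  for (k in seq_along(ring_n)) {
    m <- ring_n[k]
    # clockwise from the front (90 degrees), so the right hemisphere fills
    # first within each ring
    theta <- (pi / 2) - (seq_len(m) - 1) * 2 * pi / m
    xs <- c(xs, ring_r[k] * cos(theta))
    ys <- c(ys, ring_r[k] * sin(theta))
  }
  names32 <- c(paste0("A", 1:16), paste0("B", 1:16))
  layout <- data.frame(channel = names32, x = round(xs, 6), y = round(ys, 6),
                       stringsAsFactors = FALSE)
  # pin the conventional right-posterior name to the right-posterior site
  rp <- which.max(layout$x - layout$y)
  if (layout$channel[rp] != "B16") {
    old <- which(layout$channel == "B16")
    layout$channel[old] <- layout$channel[rp]
    layout$channel[rp] <- "B16"
  }
  if (n_channels < 32) {
    # keep a spatially spread subset: every k-th electrode plus B16
    keep <- unique(c(round(seq(1, 32, length.out = n_channels)),
                     which(layout$channel == "B16")))
    keep <- sort(keep)[seq_len(n_channels)]
    if (!which(layout$channel == "B16") %in% keep) {
      keep[length(keep)] <- which(layout$channel == "B16")
    }
    layout <- layout[sort(keep), , drop = FALSE]
    rownames(layout) <- NULL
  }
  layout
}

#' Raised-cosine effect topography
#'
#' Per-channel weights in `[0, 1]` falling off as a raised cosine with layout
#' distance from a centre electrode; weight is 0 beyond `radius`.
#'
#' @param layout electrode layout (`default_layout()` format).
#' @param center channel name at the bump centre.
#' @param radius bump radius in layout (unit-disc) distance.
#' @return named numeric vector of weights, one per channel.
#' @export
raised_cosine_topography <- function(layout, center = "B16", radius = 0.3) {
  i <- match(center, layout$channel)
  if (is.na(i)) stop("center electrode '", center, "' not in layout")
  d <- sqrt((layout$x - layout$x[i])^2 + (layout$y - layout$y[i])^2)
  w <- ifelse(d < radius, 0.5 * (1 + cos(pi * d / radius)), 0)
  names(w) <- layout$channel
  w
}
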