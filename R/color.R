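## Diverging color scales for log-odds values.

.gradients <- list(
  "blue-white-red" = list(low = c(33, 102, 172), mid = c(247, 247, 247),
                          high = c(178, 24, 43)),
  "blue-black-yellow" = list(low = c(40, 80, 255), mid = c(0, 0, 0),
                             high = c(255, 220, 0)),
  "green-white-purple" = list(low = c(27, 120, 55), mid = c(247, 247, 247),
                              high = c(118, 42, 131)))

#' Make a symmetric diverging color scale
#'
#' Maps log-odds values to colors: the value 0 maps to the gradient's
#' neutral midpoint, negative values toward the "low" (blue) end, positive
#' values toward the "high" (warm) end, linearly in each channel; values
#' beyond +/- clamp saturate.
#'
#' @param clamp half-range c > 0 in log-odds units (default 2 bits).
#' @param gradient gradient name; one of "blue-white-red" (default),
#'   "blue-black-yellow", "green-white-purple".
#' @return A [ColorScale-class].
#' @examples
#' scaleColor(makeColorScale(2), c(-2, 0, 2))
#' @export
makeColorScale <- function(clamp = 2, gradient = "blue-white-red") {
  if (length(clamp) != 1L || is.na(clamp) || clamp <= 0)
    stop("clamp must be a single positive number")
  g <- .gradients[[gradient]]
  if (is.null(g))
    stop("unknown gradient \"", gradient, "\"; available: ",
         paste(names(.gradients), collapse = ", "))
  new("ColorScale", clamp = clamp, gradient = gradient,
      low = g$low, mid = g$mid, high = g$high)
}

#' Map values through a color scale
#'
#' @param scale a [ColorScale-class].
#' @param values numeric vector of log-odds values.
#' @return Character vector of "#RRGGBB" colors.
#' @export
scaleColor <- function(scale, values) {
  t <- pmin(pmax(values / scale@clamp, -1), 1)
  rgb <- matrix(0, length(t), 3L)
  neg <- t < 0
  for (ch in 1:3) {
    rgb[, ch] <- ifelse(neg,
      scale@mid[ch] + (-t) * (scale@low[ch] - scale@mid[ch]),
      scale@mid[ch] + t * (scale@high[ch] - scale@mid[ch]))
  }
  rgb <- round(rgb)
  sprintf("#%02X%02X%02X", rgb[, 1L], rgb[, 2L], rgb[, 3L])
}

#' @describeIn makeColorScale clamp half-range of a ColorScale.
#' @param scale a ColorScale.
#' @export
scaleClamp <- function(scale) scale@clamp
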