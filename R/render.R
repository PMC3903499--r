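## SVG rendering of the color-coded development (net), paper-craft ready.

.fmt <- function(x) sprintf("%.3f", x)

#' Render the development as an SVG document
#'
#' Emits one colored polygon per cell of the code at the field's depth,
#' hierarchical prefix labels at the centroids of the depth-`labelDepth`
#' cells, optional glue flaps along the three boundary sides for folding
#' the printed net into a tetrahedron, and a color-bar legend. Rendering
#' is a pure function of its inputs: identical inputs give byte-identical
#' documents.
#'
#' @param field a [LogOddsField-class]; its k sets the subdivision depth.
#' @param scale a [ColorScale-class] (default: clamp 2 bits,
#'   blue-white-red).
#' @param labelDepth depth of the prefix labels (default 3, i.e. the 64
#'   trinucleotide prefixes); 0 suppresses labels. Must not exceed k.
#' @param flaps draw glue flaps (default TRUE).
#' @param file optional path; when given the document is written there.
#' @return Invisibly, the SVG document as a character vector of lines.
#' @export
renderDevelopment <- function(field, scale = makeColorScale(),
                              labelDepth = 3L, flaps = TRUE, file = NULL) {
  if (!is(field, "LogOddsField")) stop("field must be a LogOddsField")
  if (!is(scale, "ColorScale")) stop("scale must be a ColorScale")
  k <- field@k
  if (length(labelDepth) != 1L || is.na(labelDepth) || labelDepth < 0L ||
      labelDepth != as.integer(labelDepth))
    stop("labelDepth must be a single integer >= 0")
  labelDepth <- as.integer(labelDepth)
  if (labelDepth > k)
    stop("labelDepth (", labelDepth, ") must not exceed k (", k, ")")

  code <- tetraGrayCode(k)
  vals <- field@values[code@kmers]
  cols <- scaleColor(scale, vals)

  ## layout: base triangle edge S, margin around it, legend strip below
  S <- 1024
  margin <- 0.08 * S
  legendH <- 0.12 * S
  W <- S + 2 * margin
  triH <- S * sqrt(3) / 2
  H <- triH + 2 * margin + legendH
  ## device coordinates: y flipped
  dx <- function(x) margin + x * S
  dy <- function(y) margin + triH - y * S

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s">'),
            .fmt(W), .fmt(H), .fmt(W), .fmt(H)),
    sprintf('<rect width="%s" height="%s" fill="#FFFFFF"/>',
            .fmt(W), .fmt(H)))

  V <- code@vertices
  pts <- sprintf("%s,%s %s,%s %s,%s",
                 .fmt(dx(V[, 1L])), .fmt(dy(V[, 2L])),
                 .fmt(dx(V[, 3L])), .fmt(dy(V[, 4L])),
                 .fmt(dx(V[, 5L])), .fmt(dy(V[, 6L])))
  out <- c(out, '<g stroke="none">',
           sprintf('<polygon class="cell" points="%s" fill="%s"/>',
                   pts, cols),
           '</g>')

  ## flaps: one per side, on the first half-edge walking A->B->C->A;
  ## trapezoids with 45-degree cut ends, width 5 percent of the base edge
  if (isTRUE(flaps)) {
    corners <- list(TRIANGLE_A, TRIANGLE_B, TRIANGLE_C)
    fl <- character(0)
    for (side in 1:3) {
      p <- corners[[side]]
      q <- corners[[side %% 3L + 1L]]
      mid <- (p + q) / 2
      dir <- (q - p) / sqrt(sum((q - p)^2))
      nrm <- c(dir[2L], -dir[1L])  # outward normal (triangle is CCW)
      w <- 0.05
      poly <- rbind(p, mid, mid - dir * w + nrm * w, p + dir * w + nrm * w)
      fl <- c(fl, sprintf('<polygon class="flap" points="%s"/>',
        paste(sprintf("%s,%s", .fmt(dx(poly[, 1L])), .fmt(dy(poly[, 2L]))),
              collapse = " ")))
    }
    out <- c(out,
             '<g fill="none" stroke="#888888" stroke-width="1.2">', fl,
             '</g>')
  }

  ## cut outline of the net
  tri <- rbind(TRIANGLE_A, TRIANGLE_B, TRIANGLE_C)
  out <- c(out, sprintf(
    '<polygon class="outline" points="%s" fill="none" stroke="#000000" stroke-width="1.6"/>',
    paste(sprintf("%s,%s", .fmt(dx(tri[, 1L])), .fmt(dy(tri[, 2L]))),
          collapse = " ")))

  ## hierarchical prefix labels at the centroids of depth-labelDepth cells
  if (labelDepth > 0L) {
    lab <- tetraGrayCode(labelDepth)
    cx <- rowMeans(lab@vertices[, c(1L, 3L, 5L), drop = FALSE])
    cy <- rowMeans(lab@vertices[, c(2L, 4L, 6L), drop = FALSE])
    fs <- S / 2^labelDepth * 0.22
    out <- c(out,
      sprintf('<g font-family="Helvetica,Arial,sans-serif" font-size="%s" text-anchor="middle" fill="#000000" fill-opacity="0.55">',
              .fmt(fs)),
      sprintf('<text class="prefix-label" x="%s" y="%s">%s</text>',
              .fmt(dx(cx)), .fmt(dy(cy) + fs * 0.35), lab@kmers),
      '</g>')
  }

  ## legend: horizontal color bar with ticks at -c, 0, +c
  nSwatch <- 64L
  lw <- 0.5 * S
  lx0 <- margin + 0.25 * S
  ly0 <- triH + margin + 0.45 * legendH
  lh <- 0.3 * legendH
  tv <- scale@clamp * (2 * (seq_len(nSwatch) - 0.5) / nSwatch - 1)
  sw <- scaleColor(scale, tv)
  xs <- lx0 + (seq_len(nSwatch) - 1L) * lw / nSwatch
  out <- c(out, '<g class="legend">',
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
            .fmt(xs), .fmt(ly0), .fmt(lw / nSwatch + 0.5), .fmt(lh), sw),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#000000" stroke-width="1"/>',
            .fmt(lx0), .fmt(ly0), .fmt(lw), .fmt(lh)),
    sprintf('<g font-family="Helvetica,Arial,sans-serif" font-size="%s" text-anchor="middle" fill="#000000">',
            .fmt(0.028 * S)),
    sprintf('<text x="%s" y="%s">%s</text>',
            .fmt(c(lx0, lx0 + lw / 2, lx0 + lw)),
            .fmt(rep(ly0 + lh + 0.035 * S, 3L)),
            c(sprintf("-%g", scale@clamp), "0",
              sprintf("+%g", scale@clamp))),
    sprintf('<text x="%s" y="%s">log2 odds ratio</text>',
            .fmt(lx0 + lw / 2), .fmt(ly0 - 0.012 * S)),
    '</g>', '</g>')

  out <- c(out, "</svg>")
  if (!is.null(file))
    writeLines(out, file, useBytes = TRUE)
  invisible(out)
}
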