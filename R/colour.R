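#' CIELAB chroma and hue angle
#'
#' Converts the chromatic plane of a CIELAB coordinate to polar form:
#' chroma C*ab = sqrt(a*^2 + b*^2) (colourfulness) and hue angle
#' h_ab = atan2(b*, a*) in degrees mapped to \[0, 360) (colour type).
#' The achromatic point a* = b* = 0 has hue 0 by convention, since any
#' angle is degenerate there.
#'
#' @param L,a,b CIELAB coordinates. `L` (lightness, 0-100) is accepted for
#'   interface symmetry but does not enter the polar form; vectors recycle.
#' @return data.frame with columns `chroma` and `hue_deg`.
#' @examples
#' derive_chroma_hue(58.1, 12.2, 64.5)  # sunflower pollen: C 65.6, h 79.3
#' @export
derive_chroma_hue <- function(L = NULL, a, b) {
  stopifnot(is.finite(a), is.finite(b))
  chroma <- sqrt(a^2 + b^2)
  hue <- atan2(b, a) * 180 / pi
  hue <- ifelse(hue < 0, hue + 360, hue)
  hue[chroma == 0] <- 0
  data.frame(chroma = chroma, hue_deg = hue)
}

#' Perceptibility category of a CIELAB colour difference
#'
#' Categories follow the conventional ΔE*ab thresholds 1.5 / 3.0 / 6.0.
#' Boundaries are closed on the left: ΔE exactly 1.5 is "perceptible",
#' exactly 3.0 "well perceptible", exactly 6.0 "huge".
#'
#' @param delta_E non-negative ΔE*ab value(s).
#' @return character vector of categories.
#' @export
delta_e_category <- function(delta_E) {
  stopifnot(all(delta_E >= 0))
  cut(delta_E, breaks = c(-Inf, 1.5, 3.0, 6.0, Inf), right = FALSE,
      labels = c("not perceptible", "perceptible", "well perceptible",
                 "huge")) |> as.character()
}

#' Colour difference between two CIELAB coordinates
#'
#' ΔE*ab is the Euclidean distance in (L*, a*, b*); ΔC*ab the absolute
#' chroma difference; Δh_ab the absolute hue-angle difference in degrees,
#' taken on the circle as `min(d, 360 - d)`. Δh is the plain angle
#' difference, not the CIE ΔH*ab chord metric. The perceptibility category
#' is assigned from ΔE via [delta_e_category()].
#'
#' @param c1,c2 numeric length-3 vectors `(L, a, b)`.
#' @return data.frame with columns `delta_E`, `delta_C`, `delta_h`,
#'   `category`.
#' @examples
#' colour_difference(c(59.6, 6.0, 44.2), c(58.1, 12.2, 64.5))
#' @export
colour_difference <- function(c1, c2) {
  stopifnot(length(c1) == 3, length(c2) == 3,
            all(is.finite(c1)), all(is.finite(c2)))
  dE <- sqrt(sum((c1 - c2)^2))
  p1 <- derive_chroma_hue(c1[1], c1[2], c1[3])
  p2 <- derive_chroma_hue(c2[1], c2[2], c2[3])
  dC <- abs(p1$chroma - p2$chroma)
  dh <- abs(p1$hue_deg - p2$hue_deg)
  dh <- min(dh, 360 - dh)
  data.frame(delta_E = dE, delta_C = dC, delta_h = dh,
             category = delta_e_category(dE))
}

#' Pairwise colour-difference table
#'
#' Computes [colour_difference()] for every unordered pair of named mean
#' coordinates, the layout used to report inter-sample colour differences.
#'
#' @param samples data.frame with columns `sample`, `L`, `a`, `b`
#'   (one mean coordinate per sample; names must be unique).
#' @return data.frame with one row per pair: `sample_1`, `sample_2`,
#'   `delta_E`, `delta_C`, `delta_h`, `category`; pairs in upper-triangle
#'   order of the input.
#' @export
pairwise_colour_table <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample", "L", "a", "b") %in% names(samples)))
  if (nrow(samples) < 2) stop("need at least 2 samples")
  if (anyDuplicated(samples$sample))
    stop("duplicate sample names: ",
         paste(unique(samples$sample[duplicated(samples$sample)]),
               collapse = ", "))
  n <- nrow(samples)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- colour_difference(unlist(samples[i, c("L", "a", "b")]),
                           unlist(samples[j, c("L", "a", "b")]))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(sample_1 = samples$sample[i],
                       sample_2 = samples$sample[j]), d)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
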