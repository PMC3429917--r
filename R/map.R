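#' Haldane map function: centiMorgans to recombination fraction
#'
#' Converts a genetic distance in centiMorgans to the recombination
#' fraction between the flanking loci under the Haldane (no-interference)
#' model, \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param distance_cm Numeric vector of non-negative distances in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 10, 50))
#' @export
haldane_r <- function(distance_cm) {
  if (!is.numeric(distance_cm) || any(!is.finite(distance_cm)))
    stop("'distance_cm' must be finite numeric", call. = FALSE)
  if (any(distance_cm < 0))
    stop("genetic distances must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * distance_cm / 100))
}

#' Construct a genetic marker map
#'
#' A map is a data frame with one row per marker, ordered along the genome,
#' holding the marker name, its chromosome, optionally its position in cM,
#' and the recombination fraction `r_prev` to the previous marker on the
#' same chromosome (`NA` for the first marker of each chromosome).
#'
#' Either `pos` or `r_prev` must be supplied.  When both are given, the
#' explicit recombination fractions take precedence and positions are kept
#' for annotation only; when only positions are given, adjacent
#' recombination fractions are derived with [haldane_r()].
#'
#' @param marker Character vector of unique marker names.
#' @param chr Chromosome identifier per marker (coerced to character).
#'   Markers of a chromosome must be contiguous.
#' @param pos Optional numeric cM positions, strictly increasing within
#'   each chromosome.
#' @param r_prev Optional numeric vector of recombination fractions between
#'   each marker and its predecessor on the same chromosome; entries for
#'   chromosome-initial markers are ignored. Each value must lie in
#'   (0, 0.5].
#' @return An object of class `genetic_map` (a data frame with columns
#'   `marker`, `chr`, `pos`, `r_prev`).
#' @examples
#' genetic_map(paste0("m", 1:4), chr = c(1, 1, 2, 2), pos = c(0, 10, 0, 25))
#' @export
genetic_map <- function(marker, chr, pos = NULL, r_prev = NULL) {
  marker <- as.character(marker)
  chr <- as.character(chr)
  n_m <- length(marker)
  if (n_m < 2) stop("a map needs at least 2 markers", call. = FALSE)
  if (length(chr) != n_m) stop("'chr' length must match 'marker'", call. = FALSE)
  if (anyDuplicated(marker)) stop("marker names must be unique", call. = FALSE)
  if (anyDuplicated(rle(chr)$values))
    stop("markers of a chromosome must be contiguous in the map", call. = FALSE)
  if (is.null(pos) && is.null(r_prev))
    stop("supply marker positions ('pos') or adjacent recombination fractions ('r_prev')",
         call. = FALSE)

  first_of_chr <- c(TRUE, chr[-1] != chr[-n_m])

  if (!is.null(pos)) {
    pos <- as.numeric(pos)
    if (length(pos) != n_m) stop("'pos' length must match 'marker'", call. = FALSE)
    d <- c(NA_real_, diff(pos))
    d[first_of_chr] <- NA_real_
    if (any(d <= 0, na.rm = TRUE))
      stop("positions must be strictly increasing within a chromosome", call. = FALSE)
  } else {
    pos <- rep(NA_real_, n_m)
    d <- NULL
  }

  if (is.null(r_prev)) {
    r_prev <- rep(NA_real_, n_m)
    r_prev[!first_of_chr] <- haldane_r(d[!first_of_chr])
  } else {
    r_prev <- as.numeric(r_prev)
    if (length(r_prev) != n_m) stop("'r_prev' length must match 'marker'", call. = FALSE)
    r_prev[first_of_chr] <- NA_real_
    rr <- r_prev[!first_of_chr]
    if (any(!is.finite(rr)) || any(rr <= 0) || any(rr > 0.5))
      stop("recombination fractions must lie in (0, 0.5]", call. = FALSE)
  }

  out <- data.frame(marker = marker, chr = chr, pos = pos, r_prev = r_prev,
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  chrs <- rle(x$chr)$values
  cat(sprintf("Genetic map: %d markers on %d chromosome(s)\n",
              nrow(x), length(chrs)))
  print.data.frame(utils::head(as.data.frame(x), 8L), row.names = FALSE)
  if (nrow(x) > 8L) cat(sprintf("... %d more markers\n", nrow(x) - 8L))
  invisible(x)
}

# recombination fraction used when simulating the transition INTO marker j;
# 0.5 across a chromosome boundary (independent assortment)
map_transition_r <- function(map) {
  r <- map$r_prev
  r[is.na(r)] <- 0.5
  r[1] <- NA_real_
  r
}

#' Bundled dense/sparse example map
#'
#' A single-chromosome map of 34 markers mixing tightly clustered regions
#' (2 cM spacing) with sparse stretches (20 cM spacing).  Maps of this
#' shape make the location distribution of the genome-scan maximum visibly
#' non-uniform: the maximum lands less often on any one marker inside a
#' dense cluster and more often on isolated markers.  Shipped as a plain
#' CSV under `inst/extdata/map34_dense_sparse.csv` and loaded with
#' [read_map_csv()].
#'
#' @return A `genetic_map` with 34 markers.
#' @examples
#' map34 <- example_map_34()
#' nrow(map34)
#' @export
example_map_34 <- function() {
  path <- system.file("extdata", "map34_dense_sparse.csv", package = "ldtqtl",
                      mustWork = TRUE)
  read_map_csv(path)
}

#' Two-chromosome mixed-spacing example map
#'
#' Twenty markers on two chromosomes, each mixing a dense cluster
#' (2 cM spacing) with a sparse stretch (25 cM spacing).  Used throughout
#' the documentation and the calibration experiments as a small genome
#' with a clearly non-uniform location distribution.
#'
#' @return A `genetic_map` with 20 markers on chromosomes "1" and "2".
#' @export
example_map_20 <- function() {
  pos1 <- c(0, 2, 4, 6, 8, 10, 35, 60, 85, 110)   # dense head, sparse tail
  pos2 <- c(0, 25, 50, 75, 100, 102, 104, 106, 108, 110)
  genetic_map(sprintf("c%dm%02d", rep(1:2, each = 10), rep(1:10, 2)),
              chr = rep(c("1", "2"), each = 10), pos = c(pos1, pos2))
}
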