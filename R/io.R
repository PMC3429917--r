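#' Read a marker map from CSV
#'
#' Expects a header `marker,chromosome,position_cM` (cM positions,
#' converted to adjacent recombination fractions with the Haldane map
#' function) or `marker,chromosome,r_prev` (explicit recombination
#' fraction to the previous marker on the same chromosome, first marker
#' of each chromosome blank or NA).  Explicit fractions take precedence
#' when both columns are present.
#'
#' @param path CSV file path.
#' @return A [genetic_map()].
#' @export
read_map_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("marker", "chromosome") %in% names(d)))
    stop("map CSV needs 'marker' and 'chromosome' columns", call. = FALSE)
  pos <- if ("position_cm" %in% names(d)) as.numeric(d$position_cm) else NULL
  r <- if ("r_prev" %in% names(d)) as.numeric(d$r_prev) else NULL
  genetic_map(d$marker, d$chromosome, pos = pos, r_prev = r)
}

#' Write a marker map to CSV
#'
#' @param map A [genetic_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  d <- data.frame(marker = map$marker, chromosome = map$chr,
                  position_cM = map$pos, r_prev = map$r_prev)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# inverse Haldane, for writing pseudo-positions when a map was specified
# by recombination fractions only; fractions at 0.5 are nudged inward
inverse_haldane_cm <- function(r) {
  r <- pmin(r, 0.5 - 1e-12)
  -50 * log(1 - 2 * r)
}

map_positions_cm <- function(map) {
  if (!anyNA(map$pos)) return(map$pos)
  pos <- numeric(nrow(map))
  for (i in seq_len(nrow(map))) {
    pos[i] <- if (is.na(map$r_prev[i])) 0
              else pos[i - 1] + inverse_haldane_cm(map$r_prev[i])
  }
  pos
}

#' Read a cross from an R/qtl-style CSV file
#'
#' The `"csv"` cross layout of the R/qtl ecosystem: the first row names
#' phenotype column(s) followed by markers; the second row is blank under
#' phenotypes and carries the chromosome under each marker; the third row
#' carries the cM position; data rows follow, phenotypes numeric and
#' genotypes coded by letters (`A` for one homozygous class, `H` or `B`
#' for the other).
#'
#' Genotype data must be complete: any empty, `-` or `NA` cell is a hard
#' error — the threshold methodology assumes complete genotype
#' observations, and imputation is out of scope.  A marker exhibiting
#' more than two genotype codes (e.g. an F2 coding) is rejected by name.
#'
#' @param path CSV file path.
#' @param pheno Name or index of the phenotype column to analyse
#'   (default: the first).
#' @param cross_type Cross design tag for the returned population.
#' @param geno_codes Named integer vector mapping genotype letters to the
#'   0/1 coding (default `c(A = 0, H = 1, B = 1)`).
#' @return A [cross_pop()].
#' @export
read_cross_csv <- function(path, pheno = 1L,
                           cross_type = c("doubled_haploid", "backcross"),
                           geno_codes = c(A = 0L, H = 1L, B = 1L)) {
  cross_type <- match.arg(cross_type)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (nrow(raw) < 4)
    stop("cross CSV needs header, chromosome and position rows plus data",
         call. = FALSE)
  header <- trimws(as.character(raw[1, ]))
  chr_row <- trimws(as.character(raw[2, ]))
  pos_row <- trimws(as.character(raw[3, ]))
  is_pheno <- chr_row == ""
  if (!is_pheno[1])
    stop("expected phenotype column(s) first (blank chromosome row cell)",
         call. = FALSE)
  if (any(is_pheno & c(FALSE, !is_pheno[-length(is_pheno)])))
    stop("phenotype columns must precede all marker columns", call. = FALSE)
  n_ph <- sum(is_pheno)
  if (sum(!is_pheno) < 2)
    stop("cross CSV needs at least 2 marker columns", call. = FALSE)

  map <- genetic_map(header[!is_pheno], chr_row[!is_pheno],
                     pos = as.numeric(pos_row[!is_pheno]))
  dat <- raw[-(1:3), , drop = FALSE]

  ph_col <- if (is.character(pheno)) match(pheno, header[seq_len(n_ph)])
            else as.integer(pheno)
  if (is.na(ph_col) || ph_col < 1L || ph_col > n_ph)
    stop("phenotype column not found", call. = FALSE)
  ph_chr <- trimws(dat[[ph_col]])
  if (any(ph_chr %in% c("", "-", "NA")))
    stop("missing phenotype value(s); complete data are required",
         call. = FALSE)
  ph <- suppressWarnings(as.numeric(ph_chr))
  if (anyNA(ph))
    stop("non-numeric phenotype value(s)", call. = FALSE)

  gm <- dat[, !is_pheno, drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gm), ncol(gm),
                 dimnames = list(NULL, map$marker))
  for (j in seq_len(ncol(gm))) {
    cell <- trimws(gm[[j]])
    if (any(cell %in% c("", "-", "NA")))
      stop(sprintf(
        paste0("marker '%s' has missing genotype cell(s); the method ",
               "assumes complete genotype data"), map$marker[j]),
        call. = FALSE)
    unknown <- setdiff(unique(cell), names(geno_codes))
    if (length(unknown))
      stop(sprintf("marker '%s' has unrecognised genotype code(s): %s",
                   map$marker[j], paste(unknown, collapse = ", ")),
           call. = FALSE)
    g <- unname(geno_codes[cell])
    if (length(unique(g)) > 2L)
      stop(sprintf(
        "marker '%s' shows more than two genotype classes; only two-genotype crosses are supported",
        map$marker[j]), call. = FALSE)
    geno[, j] <- g
  }
  cross_pop(geno, ph, map, cross_type)
}

#' Write a cross to an R/qtl-style CSV file
#'
#' Inverse of [read_cross_csv()].  Maps without cM positions get
#' pseudo-positions accumulated through the inverse Haldane function.
#'
#' @param pop A [cross_pop()].
#' @param path Output path.
#' @param pheno_name Phenotype column name (default `"pheno"`).
#' @param codes Two genotype letters for classes 0 and 1 (default
#'   `c("A", "H")`).
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(pop, path, pheno_name = "pheno",
                            codes = c("A", "H")) {
  stopifnot(inherits(pop, "cross_pop"), length(codes) == 2L)
  pos <- map_positions_cm(pop$map)
  header <- c(pheno_name, pop$map$marker)
  chr_row <- c("", pop$map$chr)
  pos_row <- c("", format(pos, trim = TRUE))
  gl <- matrix(codes[pop$geno + 1L], nrow(pop$geno), ncol(pop$geno))
  body <- cbind(format(pop$pheno, trim = TRUE), gl)
  all_rows <- rbind(header, chr_row, pos_row, body)
  utils::write.table(all_rows, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a max-LOD permutation sample
#'
#' Writes the pairs to a two-column CSV (`delta,lambda`) plus a JSON
#' sidecar (`<path>.json`) recording `n_m`, `n_p`, `seed` and `tie_rule`,
#' so a long permutation run can be reused across threshold levels.
#'
#' @param sample A [sample_max_lod()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_maxlod_csv <- function(sample, path) {
  stopifnot(inherits(sample, "maxlod_sample"))
  utils::write.csv(data.frame(delta = sample$delta, lambda = sample$lambda),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(n_m = sample$n_m, n_p = sample$n_p, seed = sample$seed,
               tie_rule = sample$tie_rule, chunk_size = sample$chunk_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Reload a persisted max-LOD permutation sample
#'
#' @param path CSV path written by [write_maxlod_csv()].  The JSON sidecar
#'   `<path>.json` must sit next to it.
#' @return A `maxlod_sample`.
#' @export
read_maxlod_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  smp <- new_maxlod_sample(d$delta, d$lambda, n_m = meta$n_m,
                           seed = if (is.null(meta$seed)) NA_integer_
                                  else meta$seed,
                           tie_rule = meta$tie_rule %||% "random")
  smp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-marker threshold table for one GWER level
#'
#' Combines the constant genome-wide threshold, the constant-local-rate
#' conditional threshold and the location-dependent threshold into one
#' per-marker table, alongside the estimated location distribution.
#'
#' @param sample A [sample_max_lod()] result.
#' @param gamma Desired genome-wide error rate.
#' @param map Optional [genetic_map()] supplying marker names and
#'   positions.
#' @return Data frame with columns `marker`, `chromosome`, `position`,
#'   `T_cd`, `T_lambda`, `T_ldt`, `alpha`, `p_lambda`; attribute
#'   `summary` holds `gamma`, `n_p`, `seed`, `valid_range_upper`.
#' @export
threshold_table <- function(sample, gamma, map = NULL) {
  cd <- cd_threshold(sample, gamma)
  cond <- conditional_threshold(sample, gamma)
  ldt <- ldt_threshold(sample, gamma)
  ld <- ldt$location
  out <- data.frame(
    marker = if (is.null(map)) paste0("m", seq_len(sample$n_m))
             else map$marker,
    chromosome = if (is.null(map)) NA_character_ else map$chr,
    position = if (is.null(map)) NA_real_ else map_positions_cm(map),
    T_cd = cd$T, T_lambda = cond$T, T_ldt = ldt$T,
    alpha = ld$alpha, p_lambda = ld$p_lambda,
    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(gamma = gamma, n_p = sample$n_p,
                               seed = sample$seed,
                               valid_range_upper = ldt$valid_range_upper)
  out
}

#' Write a threshold table to CSV with a JSON summary sidecar
#'
#' @param tbl A [threshold_table()].
#' @param path CSV output path; the summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_threshold_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE, na = "")
  s <- attr(tbl, "summary")
  if (!is.null(s))
    jsonlite::write_json(s, paste0(path, ".json"), auto_unbox = TRUE,
                         na = "null")
  invisible(path)
}
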