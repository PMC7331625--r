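#' Read a GENEPOP genotype file
#'
#' Parses the GENEPOP dialect: a title line, one locus name per line (or one
#' comma-separated line), and `Pop`-delimited blocks of individuals, each
#' line `id , g1 g2 ...` with 2- or 3-digit allele codes. Allele code `00` /
#' `000` marks a missing gene copy and is excluded from allele counts.
#' Internally allele code `c` is stored as state `c - 1`, so states are
#' 0-based as everywhere else in the package; [write_genepop()] inverts the
#' shift, making a write/read round trip lossless.
#'
#' Each population is labelled by the id of its last individual (the GENEPOP
#' convention); duplicate labels are made unique.
#'
#' @param path Path to a GENEPOP text file.
#' @return A [multilocus_dataset()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path))
    stop(sprintf("GENEPOP file '%s' does not exist", path), call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  perr <- function(lineno, msg)
    stop(sprintf("GENEPOP parse error at line %d: %s", lineno, msg),
         call. = FALSE)
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) perr(length(lines), "no 'Pop' separator found")
  if (first_pop < 3L) perr(first_pop, "no locus names before first 'Pop'")
  loci <- trimws(unlist(strsplit(lines[2:(first_pop - 1L)], ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) perr(first_pop, "duplicated locus names")
  L <- length(loci)

  pop_starts <- which(is_pop)
  pop_ends <- c(pop_starts[-1L] - 1L, length(lines))
  samples <- list()
  half <- NA_integer_
  for (b in seq_along(pop_starts)) {
    rows <- (pop_starts[b] + 1L):pop_ends[b]
    rows <- rows[nzchar(trimws(lines[rows]))]
    if (length(rows) == 0L) perr(pop_starts[b], "empty population block")
    a1 <- matrix(NA_integer_, length(rows), L)
    a2 <- matrix(NA_integer_, length(rows), L)
    ids <- character(length(rows))
    for (i in seq_along(rows)) {
      ln <- rows[i]
      line <- lines[ln]
      cpos <- regexpr(",", line, fixed = TRUE)
      if (cpos < 0) perr(ln, "missing ',' between individual id and genotypes")
      ids[i] <- trimws(substr(line, 1L, cpos - 1L))
      g <- strsplit(trimws(substr(line, cpos + 1L, nchar(line))), "\\s+")[[1L]]
      if (length(g) != L)
        perr(ln, sprintf("expected %d genotypes, found %d", L, length(g)))
      w <- unique(nchar(g))
      if (length(w) != 1L || !w %in% c(4L, 6L))
        perr(ln, "genotypes must all use 2- or 3-digit allele codes")
      if (is.na(half)) half <- w / 2L
      else if (half != w / 2L) perr(ln, "inconsistent allele code width")
      if (any(grepl("[^0-9]", g))) perr(ln, "non-numeric allele code")
      c1 <- as.integer(substr(g, 1L, half))
      c2 <- as.integer(substr(g, half + 1L, 2L * half))
      a1[i, ] <- ifelse(c1 == 0L, NA_integer_, c1 - 1L)
      a2[i, ] <- ifelse(c2 == 0L, NA_integer_, c2 - 1L)
    }
    samples[[b]] <- pop_sample(ids[length(ids)], a1, a2, loci)
  }
  labels <- make.unique(vapply(samples, `[[`, "", "population"))
  for (b in seq_along(samples)) samples[[b]]$population <- labels[b]
  multilocus_dataset(samples)
}

#' Write genotypes as a GENEPOP file
#'
#' Internal state `s` is written as allele code `s + 1` (code 0 is reserved
#' for missing data); every individual in a block carries its population
#' label as id, so [read_genepop()] recovers the labels.
#'
#' @param x A [multilocus_dataset()] or a single `pop_sample`.
#' @param path Output path.
#' @param code_width Digits per allele code, 2 or 3.
#' @param title Title line content.
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(x, path, code_width = 3L, title = "shannonpop export") {
  if (inherits(x, "pop_sample")) x <- multilocus_dataset(list(x))
  stopifnot(inherits(x, "multilocus_dataset"), code_width %in% c(2L, 3L))
  maxcode <- 10^code_width - 1L
  out <- c(title, x$loci)
  for (s in x$samples) {
    out <- c(out, "Pop")
    code <- function(a) {
      a <- a + 1L
      a[is.na(a)] <- 0L
      if (any(a > maxcode))
        stop(sprintf("allele state too large for %d-digit codes", code_width),
             call. = FALSE)
      matrix(sprintf("%0*d", code_width, a), nrow = nrow(s$a1))
    }
    g1 <- code(s$a1); g2 <- code(s$a2)
    geno <- matrix(paste0(g1, g2), nrow = nrow(s$a1))
    out <- c(out, paste(s$population, ",", apply(geno, 1L, paste, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
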