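#' Construct a diploid SSR genotype dataset
#'
#' The central genotype container: diploid allele-size calls for individuals
#' grouped in ordered populations, with optional per-population metadata
#' (state, region, coordinates).  Allele codes are positive integers no
#' larger than 999 (3-digit Genepop coding); a missing genotype is a pair of
#' `NA`s — a call is never half-missing.
#'
#' @param alleles integer matrix with one row per individual and `2 * L`
#'   columns for `L` loci (columns `2l-1`, `2l` are the two allele copies at
#'   locus `l`).  `NA` marks missing; both copies of a call must be `NA`
#'   together.
#' @param pop factor or character of length `nrow(alleles)` assigning each
#'   individual to a population; factor level order defines population order.
#' @param id character vector of individual identifiers (default generated).
#' @param loci character vector of `L` locus names (default `L01`, ...).
#' @param meta optional population metadata `data.frame` with columns
#'   `population`, `state`, `region`, `lat`, `lon` (see
#'   [attach_metadata()]).
#' @return an object of class `genotype_dataset`.
#' @seealso [read_genepop()], [write_genepop()], [attach_metadata()]
#' @export
genotype_dataset <- function(alleles, pop, id = NULL, loci = NULL,
                             meta = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  attributes(alleles) <- attributes(alleles)["dim"] # strip stray attrs
  if (ncol(alleles) %% 2L != 0L)
    stop("'alleles' must have two columns per locus")
  n_loci <- ncol(alleles) %/% 2L
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(n_loci))
  if (length(loci) != n_loci) stop("locus name count mismatch")
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(pop))
  if (length(pop) != nrow(alleles)) stop("'pop' length mismatch")
  if (anyDuplicated(levels(pop))) stop("population IDs must be unique")
  if (is.null(id)) {
    id <- paste0(as.character(pop), "_",
                 stats::ave(seq_along(pop), pop, FUN = seq_along))
  }
  bad <- which(!is.na(alleles) & (alleles < 1L | alleles > 999L))
  if (length(bad))
    stop("allele codes must be integers in 1..999 (3-digit Genepop coding)")
  a1 <- alleles[, seq(1L, ncol(alleles), by = 2L), drop = FALSE]
  a2 <- alleles[, seq(2L, ncol(alleles), by = 2L), drop = FALSE]
  if (any(is.na(a1) != is.na(a2)))
    stop("a diploid call cannot be half-missing: both copies must be NA")
  ds <- structure(list(
    alleles = alleles,
    ind = data.frame(id = as.character(id), pop = pop,
                     stringsAsFactors = FALSE),
    loci = as.character(loci),
    meta = meta
  ), class = "genotype_dataset")
  if (!is.null(meta)) ds <- attach_metadata(ds, meta)
  ds
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d populations, %d loci\n",
              nrow(x$alleles), nlevels(x$ind$pop), length(x$loci)))
  miss <- mean(is.na(x$alleles[, seq(1, ncol(x$alleles), by = 2)]))
  cat(sprintf("  missing calls: %.1f%%; metadata: %s\n", 100 * miss,
              if (is.null(x$meta)) "none" else "attached"))
  invisible(x)
}

#' Population identifiers of a genotype dataset
#' @param ds a `genotype_dataset`
#' @return character vector of population IDs in file/definition order
#' @export
populations <- function(ds) levels(ds$ind$pop)

# two-column allele matrix for one locus (internal)
locus_alleles <- function(ds, l) {
  ds$alleles[, c(2L * l - 1L, 2L * l), drop = FALSE]
}

#' Read a Genepop-format genotype file
#'
#' Parses the classic Genepop dialect: a title line, locus names (one per
#' line or comma-separated), population blocks opened by a line equal to
#' `pop` (case-insensitive), and individual lines
#' `"<name> , <code per locus>"` where each code concatenates the two allele
#' halves in 2- or 3-digit coding (detected from code width).  `00`/`000`
#' halves are missing; a genotype with exactly one missing half is recorded
#' as wholly missing and counted in the parse report.
#'
#' @param file path to a Genepop file, or a single string containing the
#'   file's text (newlines included).
#' @return a [genotype_dataset()] whose population, individual and locus
#'   order match the file.  The attribute `parse_report` is a list with
#'   `missing_calls` (number of codes containing a missing half) and
#'   `half_missing` (number of those with exactly one missing half).
#' @export
read_genepop <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else strsplit(paste(file, collapse = "\n"), "\n")[[1]]
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("Genepop parse error: file too short")
  is_pop <- tolower(trimws(lines)) == "pop"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("Genepop parse error: zero populations")
  if (first_pop < 3L)
    stop("Genepop parse error: no locus names before line ", first_pop)
  loci <- unlist(strsplit(lines[2:(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  n_loci <- length(loci)

  pop_breaks <- which(is_pop)
  ids <- character(0); pops <- character(0)
  rows <- list(); half_missing <- 0L; missing_calls <- 0L
  width <- NA_integer_
  for (b in seq_along(pop_breaks)) {
    from <- pop_breaks[b] + 1L
    to <- if (b < length(pop_breaks)) pop_breaks[b + 1L] - 1L else length(lines)
    pop_name <- sprintf("pop%02d", b)
    for (ln in seq(from, length.out = max(0L, to - from + 1L))) {
      line <- trimws(lines[ln])
      if (!nzchar(line)) next
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2L)
        stop("Genepop parse error: no ',' separator on line ", ln)
      ind_id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "[[:space:]]+")[[1]]
      if (length(codes) != n_loci)
        stop("Genepop parse error: ", length(codes), " codes for ",
             n_loci, " loci on line ", ln)
      w <- unique(nchar(codes))
      if (length(w) != 1L || !(w %in% c(4L, 6L)))
        stop("Genepop parse error: malformed code width on line ", ln)
      if (is.na(width)) width <- w
      if (w != width)
        stop("Genepop parse error: inconsistent code width on line ", ln)
      h <- width %/% 2L
      a1 <- as.integer(substr(codes, 1L, h))
      a2 <- as.integer(substr(codes, h + 1L, width))
      if (anyNA(a1) || anyNA(a2))
        stop("Genepop parse error: non-numeric code on line ", ln)
      m1 <- a1 == 0L; m2 <- a2 == 0L
      missing_calls <- missing_calls + sum(m1 | m2)
      half_missing <- half_missing + sum(xor(m1, m2))
      a1[m1 | m2] <- NA_integer_
      a2[m1 | m2] <- NA_integer_
      rows[[length(rows) + 1L]] <- as.vector(rbind(a1, a2))
      ids <- c(ids, ind_id); pops <- c(pops, pop_name)
    }
    if (!any(pops == pop_name))
      stop("Genepop parse error: empty population block at line ",
           pop_breaks[b])
  }
  alleles <- do.call(rbind, rows)
  ds <- genotype_dataset(alleles, pop = factor(pops, levels = unique(pops)),
                         id = ids, loci = loci)
  attr(ds, "parse_report") <- list(missing_calls = missing_calls,
                                   half_missing = half_missing)
  ds
}

#' Write a genotype dataset in canonical Genepop format
#'
#' Emits one locus name per line, `pop` separators, 3-digit zero-padded
#' allele coding and `000000` for missing calls, so that
#' `read_genepop(write_genepop(ds))` is the identity on the data model.
#'
#' @param ds a [genotype_dataset()]
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @param title title line (first line of the file).
#' @return the file text as a single string (invisibly when `file` given).
#' @export
write_genepop <- function(ds, file = NULL, title = "resmosaic export") {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (any(!is.na(ds$alleles) & ds$alleles > 999L))
    stop("allele code > 999 cannot be represented in 3-digit Genepop coding")
  tab <- table(ds$ind$pop)
  if (any(tab == 0L))
    stop("population with 0 individuals cannot be written: ",
         paste(names(tab)[tab == 0L], collapse = ", "))
  codes <- ds$alleles
  codes[is.na(codes)] <- 0L
  a1 <- codes[, seq(1L, ncol(codes), by = 2L), drop = FALSE]
  a2 <- codes[, seq(2L, ncol(codes), by = 2L), drop = FALSE]
  code_str <- matrix(sprintf("%03d%03d", a1, a2), nrow = nrow(codes))
  out <- c(title, ds$loci)
  for (p in levels(ds$ind$pop)) {
    out <- c(out, "pop")
    for (i in which(ds$ind$pop == p)) {
      out <- c(out, paste0(ds$ind$id[i], " ,  ",
                           paste(code_str[i, ], collapse = " ")))
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(text, file, sep = ""); return(invisible(text)) }
  text
}

#' Read a delimited phenotype table
#'
#' Expects a header row with columns `individual`, `population`,
#' `replicate`, `dose`, `survival` (optional `height`, `leaves`); comma
#' delimiter by default, tab accepted (sniffed from the header).  Rows with
#' missing survival are dropped and counted in the `n_dropped` attribute.
#'
#' @param file path or single text string.
#' @param metadata optional population metadata; when supplied, any
#'   phenotype row whose population is absent from the metadata is an error.
#' @return a `data.frame` with typed columns; attribute `n_dropped` gives
#'   the number of rows removed for missing survival.
#' @export
read_phenotypes <- function(file, metadata = NULL) {
  txt <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else strsplit(paste(file, collapse = "\n"), "\n")[[1]]
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0L) {
    out <- data.frame(individual = character(0), population = character(0),
                      replicate = integer(0), dose = numeric(0),
                      survival = integer(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  sep <- if (grepl("\t", txt[1])) "\t" else ","
  tbl <- utils::read.table(text = txt, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("individual", "population", "replicate", "dose", "survival")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  n_dropped <- sum(is.na(tbl$survival))
  tbl <- tbl[!is.na(tbl$survival), , drop = FALSE]
  tbl$dose <- as.numeric(tbl$dose)
  if (anyNA(tbl$dose) || any(tbl$dose < 0))
    stop("dose must be a nonnegative number")
  if (!all(tbl$survival %in% c(0, 1)))
    stop("survival must be binary 0/1")
  tbl$survival <- as.integer(tbl$survival)
  tbl$replicate <- as.integer(tbl$replicate)
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(tbl$population), metadata$population)
    if (length(unknown))
      stop("unknown population ID in phenotypes: ",
           paste(unknown, collapse = ", "))
  }
  rownames(tbl) <- NULL
  attr(tbl, "n_dropped") <- n_dropped
  tbl
}

#' State-to-region mapping of the sampling design
#'
#' Fixed mapping used throughout: Indiana and Ohio are Midwestern (`MW`);
#' Virginia, North Carolina, South Carolina and Tennessee are Southeastern
#' (`SE`).
#'
#' @param state character vector of two-letter state codes.
#' @return character vector of regions (`MW` or `SE`).
#' @export
region_from_state <- function(state) {
  map <- c(IN = "MW", OH = "MW", VA = "SE", NC = "SE", SC = "SE", TN = "SE")
  out <- unname(map[as.character(state)])
  if (anyNA(out))
    stop("state not in study design (no region mapping): ",
         paste(unique(state[is.na(out)]), collapse = ", "))
  out
}

#' Attach population metadata to a dataset or phenotype table
#'
#' Joins state/region/coordinate metadata onto a [genotype_dataset()] or a
#' phenotype `data.frame`.  Region, when absent from the metadata, is
#' derived from state through the fixed design mapping
#' ([region_from_state()]); a metadata `region` column overrides it.
#'
#' @param x a `genotype_dataset` or phenotype `data.frame` with a
#'   `population` column.
#' @param metadata `data.frame` with columns `population`, `state`,
#'   optional `region`, `lat`, `lon`.
#' @return `x` with metadata attached (`$meta` for datasets; joined columns
#'   for tables).
#' @export
attach_metadata <- function(x, metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("population", "state", "lat", "lon")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(metadata$region) || all(is.na(metadata$region))) {
    metadata$region <- region_from_state(metadata$state)
  } else {
    idx <- is.na(metadata$region)
    if (any(idx)) metadata$region[idx] <- region_from_state(metadata$state[idx])
  }
  if (!all(metadata$region %in% c("MW", "SE")))
    stop("region must be MW or SE")
  if (any(abs(metadata$lat) > 90) || any(abs(metadata$lon) > 180))
    stop("coordinates out of range")
  if (anyDuplicated(metadata$population))
    stop("duplicated population in metadata")
  metadata <- metadata[, c("population", "state", "region", "lat", "lon")]
  if (inherits(x, "genotype_dataset")) {
    unknown <- setdiff(populations(x), metadata$population)
    if (length(unknown))
      stop("populations missing from metadata: ",
           paste(unknown, collapse = ", "))
    x$meta <- metadata[match(populations(x), metadata$population), ]
    rownames(x$meta) <- NULL
    return(x)
  }
  if (!is.data.frame(x) || is.null(x$population))
    stop("x must be a genotype_dataset or a table with a 'population' column")
  unknown <- setdiff(unique(x$population), metadata$population)
  if (length(unknown))
    stop("populations missing from metadata: ",
         paste(unknown, collapse = ", "))
  j <- match(x$population, metadata$population)
  x$state <- metadata$state[j]
  x$region <- metadata$region[j]
  x$lat <- metadata$lat[j]
  x$lon <- metadata$lon[j]
  x
}
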