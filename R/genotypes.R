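#' Diploid microsatellite genotype table
#'
#' The central genotype container: one row per individual, one column pair per
#' locus, plus group labels, optional population labels, and projected metric
#' x/y coordinates. Allele calls are stored as two integer matrices `a1`, `a2`
#' (allele sizes, `a1 <= a2` so pairs are order-free); a locus is missing for
#' an individual iff both alleles are `NA` (half-calls are rejected).
#'
#' @param ind_id character vector of unique individual identifiers.
#' @param group_id character vector of sampling-group labels (non-empty).
#' @param x,y numeric projected coordinates in metres (finite).
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes;
#'   positive integers or `NA`; `NA` patterns of `a1` and `a2` must agree.
#' @param pop_id optional character vector of population labels.
#' @param loci locus names; defaults to `colnames(a1)` or `L1..Lk`.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(ind_id, group_id, x, y, a1, a2,
                           pop_id = NULL, loci = NULL) {
  n <- length(ind_id)
  a1 <- unname(as.matrix(a1)); a2 <- unname(as.matrix(a2))
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  .check(length(group_id) == n && length(x) == n && length(y) == n,
         "ind_id, group_id, x, y must have equal length")
  .check(nrow(a1) == n && nrow(a2) == n && ncol(a1) == ncol(a2),
         "allele matrices must be %d x n_loci", n)
  .check(!anyDuplicated(ind_id), "duplicate individual ids")
  .check(all(nzchar(group_id)) && !anyNA(group_id), "group_id must be non-empty")
  .check(all(is.finite(x)) && all(is.finite(y)),
         "coordinates must be finite; offending rows: %s",
         paste(which(!is.finite(x) | !is.finite(y)), collapse = ","))
  .check(identical(is.na(a1), is.na(a2)),
         "half-calls not allowed: NA patterns of a1 and a2 differ")
  ok <- is.na(a1) | a1 > 0L
  .check(all(ok) && all(is.na(a2) | a2 > 0L), "allele sizes must be positive")
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  .check(length(loci) == ncol(a1), "loci names must match allele columns")
  # order-free storage
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(ind_id, loci)
  if (!is.null(pop_id)) {
    .check(length(pop_id) == n, "pop_id length mismatch")
    pop_id <- as.character(pop_id)
  }
  structure(list(ind_id = as.character(ind_id),
                 group_id = as.character(group_id),
                 pop_id = pop_id,
                 x = as.numeric(x), y = as.numeric(y),
                 a1 = lo, a2 = hi, loci = as.character(loci)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, %d groups\n",
              length(x$ind_id), length(x$loci),
              length(unique(x$group_id))))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", sum(is.na(x$a1)),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param table a [genotype_table()].
#' @return integer count.
#' @export
n_ind <- function(table) length(table$ind_id)

#' @rdname n_ind
#' @export
n_loci <- function(table) length(table$loci)

#' Subset a genotype table by individuals
#' @param table a [genotype_table()].
#' @param idx logical or integer index over individuals.
#' @return a new `genotype_table`.
#' @export
subset_individuals <- function(table, idx) {
  genotype_table(table$ind_id[idx], table$group_id[idx],
                 table$x[idx], table$y[idx],
                 table$a1[idx, , drop = FALSE], table$a2[idx, , drop = FALSE],
                 pop_id = if (!is.null(table$pop_id)) table$pop_id[idx],
                 loci = table$loci)
}

#' Read a genotype table from GenePop or CSV
#'
#' Two dialects are supported. The GenePop dialect is the community-standard
#' text format: a title line, one locus name per line (or one comma-separated
#' line), `Pop` separator lines, and per individual `id ,  aaabbb ...` with
#' three digits per allele and `000000` for missing. GenePop carries no
#' coordinates, so individuals read from it get `x = y = 0`; the CSV dialect
#' (`individual_id, group_id[, population_id], x, y, <locus>_a, <locus>_b`) is
#' lossless and is the package's native on-disk form.
#'
#' @param path path to the file.
#' @param format `"genepop"` or `"csv"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("genepop", "csv")) {
  format <- match.arg(format)
  .check(file.exists(path), "file not found: %s", path)
  if (format == "genepop") .read_genepop(path) else .read_genotypes_csv(path)
}

.read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .check(length(lines) >= 3, "GenePop file too short: %s", path)
  body <- lines[-1]  # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  .check(!is.na(first_pop), "no 'Pop' separator found in %s", path)
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  loci <- if (length(locus_lines) == 1L && grepl(",", locus_lines)) {
    trimws(strsplit(locus_lines, ",")[[1]])
  } else locus_lines
  L <- length(loci)
  pop_index <- cumsum(is_pop)
  ind_lines <- which(!is_pop & pop_index > 0)
  ids <- character(0); grp <- character(0)
  a1 <- a2 <- NULL
  for (li in ind_lines) {
    ln <- body[li]
    parts <- strsplit(ln, ",")[[1]]
    .check(length(parts) == 2, "GenePop line %d: expected 'id , alleles'",
           li + 1L)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    .check(length(codes) == L,
           "GenePop line %d ('%s'): %d allele codes, expected %d loci",
           li + 1L, id, length(codes), L)
    w <- nchar(codes)
    .check(all(w == 6L),
           "GenePop line %d ('%s'): allele code width %s not 6 (3 digits/allele)",
           li + 1L, id, paste(unique(w[w != 6L]), collapse = ","))
    x1 <- as.integer(substr(codes, 1, 3))
    x2 <- as.integer(substr(codes, 4, 6))
    miss <- x1 == 0L & x2 == 0L
    .check(all(miss | (x1 > 0L & x2 > 0L)),
           "GenePop line %d ('%s'): half-missing code", li + 1L, id)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id); grp <- c(grp, paste0("pop", pop_index[li]))
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  # derive group labels from shared id prefixes (writer emits <group>_<i>)
  pref <- sub("_[^_]*$", "", ids)
  by_grp <- split(pref, grp)
  if (all(vapply(by_grp, function(p) length(unique(p)) == 1L, logical(1))) &&
      !anyDuplicated(vapply(by_grp, `[`, character(1), 1))) {
    lab <- vapply(by_grp, `[`, character(1), 1)
    grp <- lab[grp]
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(ids, grp, x = rep(0, length(ids)), y = rep(0, length(ids)),
                 a1 = a1, a2 = a2, loci = loci)
}

.read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual_id", "group_id", "x", "y")
  .check(all(need %in% names(df)), "CSV missing columns: %s",
         paste(setdiff(need, names(df)), collapse = ","))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
               !is.finite(suppressWarnings(as.numeric(df$y))))
  .check(length(bad) == 0, "non-finite coordinates at row(s): %s",
         paste(bad, collapse = ","))
  acols <- grep("_a$", names(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  .check(all(paste0(loci, "_b") %in% names(df)),
         "CSV allele columns not paired (<locus>_a / <locus>_b)")
  a1 <- as.matrix(df[paste0(loci, "_a")])
  a2 <- as.matrix(df[paste0(loci, "_b")])
  genotype_table(df$individual_id, df$group_id,
                 as.numeric(df$x), as.numeric(df$y), a1, a2,
                 pop_id = if ("population_id" %in% names(df)) df$population_id,
                 loci = loci)
}

#' Write a genotype table
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @param format `"csv"` (lossless) or `"genepop"` (drops coordinates and
#'   population labels; allele sizes must be < 1000).
#' @param title title line for GenePop output.
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(table, path, format = c("csv", "genepop"),
                            title = "costsweep export") {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(individual_id = table$ind_id, group_id = table$group_id,
                     stringsAsFactors = FALSE)
    if (!is.null(table$pop_id)) df$population_id <- table$pop_id
    df$x <- table$x; df$y <- table$y
    for (j in seq_along(table$loci)) {
      df[[paste0(table$loci[j], "_a")]] <- table$a1[, j]
      df[[paste0(table$loci[j], "_b")]] <- table$a2[, j]
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    .check(all(is.na(table$a1) | table$a1 < 1000) &&
           all(is.na(table$a2) | table$a2 < 1000),
           "GenePop 3-digit codes cannot hold allele sizes >= 1000")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(title, con)
    writeLines(table$loci, con)
    for (g in unique(table$group_id)) {
      writeLines("Pop", con)
      for (i in which(table$group_id == g)) {
        codes <- ifelse(is.na(table$a1[i, ]), "000000",
                        sprintf("%03d%03d", table$a1[i, ], table$a2[i, ]))
        writeLines(sprintf("%s ,  %s", table$ind_id[i],
                           paste(codes, collapse = " ")), con)
      }
    }
  }
  invisible(path)
}
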