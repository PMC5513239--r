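#' Genotype panels
#'
#' A `geno_panel` holds a microsatellite locus panel together with the
#' multilocus genotypes of a set of individuals. Alleles are opaque integer
#' labels (fragment-size units); a locus is either fully typed (both allele
#' copies present) or missing — half-calls are rejected. Internally genotypes
#' are stored as two aligned integer matrices (individuals x loci) with the
#' smaller allele first, so that genotype comparisons are order-insensitive.
#'
#' @param ind Data frame with columns `id` (unique), `sex`
#'   (`"female"`, `"male"` or `"unknown"`), `year` (integer) and optionally
#'   `sampled` (logical, default `TRUE`).
#' @param a1,a2 Integer matrices of first/second allele copies, one row per
#'   individual, one column per locus. `NA` in both marks a missing locus.
#' @param loci Data frame with columns `locus` and `role`
#'   (`"primary"` or `"confirmation"`). Defaults to all-primary.
#'
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(ind, a1, a2, loci = NULL) {
  ind <- tibble::as_tibble(ind)
  stopifnot(all(c("id", "sex", "year") %in% names(ind)))
  if (!"sampled" %in% names(ind)) ind$sampled <- TRUE
  ind$id <- as.character(ind$id)
  if (anyDuplicated(ind$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  bad_sex <- setdiff(unique(ind$sex), c("female", "male", "unknown"))
  if (length(bad_sex)) stop("invalid sex label(s): ", paste(bad_sex, collapse = ", "))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(nrow(a1) == nrow(ind), identical(dim(a1), dim(a2)))
  if (is.null(loci)) {
    nm <- colnames(a1)
    if (is.null(nm)) nm <- paste0("L", seq_len(ncol(a1)))
    loci <- tibble::tibble(locus = nm, role = "primary")
  }
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("locus", "role") %in% names(loci)))
  if (anyDuplicated(loci$locus)) stop("duplicate locus names in panel")
  stopifnot(ncol(a1) == nrow(loci))
  dimnames(a1) <- dimnames(a2) <- list(ind$id, loci$locus)
  # no half-calls
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-called genotype for individual '", ind$id[w[1]],
         "' at locus '", loci$locus[w[2]], "'")
  }
  # canonical order: a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  structure(list(loci = loci, ind = ind, a1 = a1, a2 = a2),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat("<geno_panel> ", nrow(x$ind), " individuals, ", nrow(x$loci), " loci (",
      sum(x$loci$role == "primary"), " primary, ",
      sum(x$loci$role == "confirmation"), " confirmation)\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat("  years: ", paste(sort(unique(x$ind$year)), collapse = ", "),
      "; missing genotypes: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel A `geno_panel`.
#' @return Integer count.
#' @export
n_ind <- function(panel) nrow(panel$ind)

#' Subset a panel by id, year or logical mask
#'
#' @param panel A `geno_panel`.
#' @param ids,years Optional id / year filters.
#' @param keep Optional logical vector over individuals.
#' @return A `geno_panel` with the selected individuals.
#' @export
panel_subset <- function(panel, ids = NULL, years = NULL, keep = NULL) {
  sel <- rep(TRUE, n_ind(panel))
  if (!is.null(ids)) sel <- sel & panel$ind$id %in% ids
  if (!is.null(years)) sel <- sel & panel$ind$year %in% years
  if (!is.null(keep)) sel <- sel & keep
  geno_panel(panel$ind[sel, , drop = FALSE],
             panel$a1[sel, , drop = FALSE],
             panel$a2[sel, , drop = FALSE],
             panel$loci)
}

#' Extract one individual's multilocus genotype
#'
#' @param panel A `geno_panel`.
#' @param id Individual id.
#' @return List with named integer vectors `a1` and `a2` (NA = missing locus).
#' @export
panel_genotype <- function(panel, id) {
  i <- match(id, panel$ind$id)
  if (is.na(i)) stop("unknown individual id '", id, "'")
  list(a1 = panel$a1[i, ], a2 = panel$a2[i, ])
}

locus_index <- function(panel, loci = NULL) {
  if (is.null(loci)) return(seq_len(nrow(panel$loci)))
  if (is.character(loci) && length(loci) == 1 &&
      loci %in% c("primary", "confirmation")) {
    return(which(panel$loci$role == loci))
  }
  idx <- match(loci, panel$loci$locus)
  if (anyNA(idx)) stop("unknown locus name(s): ",
                       paste(loci[is.na(idx)], collapse = ", "))
  idx
}

#' Read a genotype table
#'
#' Wide dialect (default): UTF-8 delimited text, header
#' `id, sex, year, <locus>_1, <locus>_2, ...`, one row per individual, the
#' missing-allele code (default `"0"`) in both columns marking a missing
#' locus. A minimal Genepop dialect (3-digit concatenated alleles, `Pop`
#' blocks) is available via `dialect = "genepop"`; Genepop carries no
#' sex/year metadata so those default to `"unknown"` / `NA`.
#'
#' @param path File path.
#' @param sep Field delimiter (wide dialect), default tab.
#' @param missing_code Allele code marking missing data, default `"0"`.
#' @param roles Optional named character vector `locus -> role`; loci absent
#'   from it default to `"primary"`.
#' @param dialect `"wide"` or `"genepop"`.
#' @return A [geno_panel()].
#' @export
load_panel <- function(path, sep = "\t", missing_code = "0", roles = NULL,
                       dialect = c("wide", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "genepop") return(load_genepop(path, roles))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  nm <- names(tab)
  if (length(nm) < 5 || !identical(nm[1:3], c("id", "sex", "year"))) {
    stop("genotype table must start with columns id, sex, year")
  }
  acols <- nm[-(1:3)]
  if (length(acols) %% 2 != 0) {
    stop("odd number of allele columns (", length(acols),
         "): expected two per locus")
  }
  l1 <- acols[seq(1, length(acols), by = 2)]
  l2 <- acols[seq(2, length(acols), by = 2)]
  loc_names <- sub("_1$", "", l1)
  if (!identical(paste0(loc_names, "_1"), l1) ||
      !identical(paste0(loc_names, "_2"), l2)) {
    stop("allele columns must come in <locus>_1, <locus>_2 order")
  }
  parse_alleles <- function(cols) {
    m <- as.matrix(tab[, cols, drop = FALSE])
    m[m == missing_code] <- NA
    suppressWarnings(out <- matrix(as.integer(m), nrow = nrow(m)))
    bad <- is.na(out) & !is.na(m)
    if (any(bad)) {
      row <- which(rowSums(bad) > 0)[1]
      stop("unparseable allele in line ", row + 1L, " of ", path)
    }
    out
  }
  a1 <- parse_alleles(l1); a2 <- parse_alleles(l2)
  colnames(a1) <- colnames(a2) <- loc_names
  role <- rep("primary", length(loc_names))
  if (!is.null(roles)) {
    hit <- loc_names %in% names(roles)
    role[hit] <- unname(roles[loc_names[hit]])
  }
  sex <- tolower(tab$sex)
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  sex[!sex %in% c("female", "male")] <- "unknown"
  ind <- tibble::tibble(id = tab$id, sex = sex,
                        year = as.integer(tab$year), sampled = TRUE)
  geno_panel(ind, a1, a2, tibble::tibble(locus = loc_names, role = role))
}

load_genepop <- function(path, roles = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # line 1 = title; locus names until first 'Pop' (one per line or comma list)
  body <- lines[-1]
  pop_at <- which(toupper(trimws(body)) == "POP")
  if (!length(pop_at)) stop("no Pop line in Genepop file")
  loc_names <- trimws(unlist(strsplit(body[seq_len(pop_at[1] - 1)], ",")))
  recs <- body[-seq_len(pop_at[1] - 1)]
  recs <- recs[toupper(trimws(recs)) != "POP"]
  ids <- character(0); rows1 <- list(); rows2 <- list()
  for (r in recs) {
    parts <- strsplit(r, ",")[[1]]
    if (length(parts) < 2) stop("malformed Genepop record: ", r)
    ids <- c(ids, trimws(parts[1]))
    g <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    if (length(g) != length(loc_names)) {
      stop("Genepop record for '", trimws(parts[1]), "' has ", length(g),
           " loci, expected ", length(loc_names))
    }
    w <- nchar(g) / 2
    a1 <- as.integer(substr(g, 1, w)); a2 <- as.integer(substr(g, w + 1, 2 * w))
    a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
    rows1[[length(rows1) + 1L]] <- a1
    rows2[[length(rows2) + 1L]] <- a2
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  colnames(a1) <- colnames(a2) <- loc_names
  role <- rep("primary", length(loc_names))
  if (!is.null(roles)) {
    hit <- loc_names %in% names(roles)
    role[hit] <- unname(roles[loc_names[hit]])
  }
  ind <- tibble::tibble(id = ids, sex = "unknown", year = NA_integer_,
                        sampled = TRUE)
  geno_panel(ind, a1, a2, tibble::tibble(locus = loc_names, role = role))
}

#' Write a genotype table (wide dialect)
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p, f))` round-trips.
#'
#' @param panel A `geno_panel`.
#' @param path Output file path.
#' @param sep Field delimiter, default tab.
#' @param missing_code Code written for missing alleles, default `"0"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = "\t", missing_code = "0") {
  fmt <- function(m) {
    m <- matrix(as.character(m), nrow = nrow(m))
    m[is.na(m)] <- missing_code
    m
  }
  a1 <- fmt(panel$a1); a2 <- fmt(panel$a2)
  out <- data.frame(id = panel$ind$id, sex = panel$ind$sex,
                    year = panel$ind$year, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_len(nrow(panel$loci))) {
    out[[paste0(panel$loci$locus[j], "_1")]] <- a1[, j]
    out[[paste0(panel$loci$locus[j], "_2")]] <- a2[, j]
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele frequencies from a panel
#'
#' Counts gene copies (two per non-missing genotype) and normalizes per
#' locus; missing genotypes are excluded from the denominator.
#'
#' @param panel A `geno_panel`.
#' @param loci Optional locus subset (names, or `"primary"`/`"confirmation"`).
#' @return Named list, one element per locus: a named numeric vector of
#'   allele frequencies (names = allele labels), class `allele_freqs`.
#' @export
allele_frequencies <- function(panel, loci = NULL) {
  idx <- locus_index(panel, loci)
  out <- lapply(idx, function(j) {
    alleles <- c(panel$a1[, j], panel$a2[, j])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) {
      stop("locus '", panel$loci$locus[j], "' has no non-missing genotypes")
    }
    tab <- table(alleles)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(out) <- panel$loci$locus[idx]
  structure(out, class = "allele_freqs")
}

#' Per-locus allele counts and observed heterozygosity
#'
#' @param panel A non-empty `geno_panel`.
#' @return List with `per_locus` (tibble: locus, role, n_typed, A, Ho) and
#'   `panel` (tibble of mean and SD of A and Ho across loci, overall and by
#'   role).
#' @export
diversity_summary <- function(panel) {
  if (n_ind(panel) == 0) stop("empty panel")
  per <- lapply(seq_len(nrow(panel$loci)), function(j) {
    ok <- !is.na(panel$a1[, j])
    n <- sum(ok)
    A <- length(unique(c(panel$a1[ok, j], panel$a2[ok, j])))
    Ho <- if (n) mean(panel$a1[ok, j] != panel$a2[ok, j]) else NA_real_
    tibble::tibble(locus = panel$loci$locus[j], role = panel$loci$role[j],
                   n_typed = n, A = A, Ho = Ho)
  })
  per <- dplyr::bind_rows(per)
  summarize_block <- function(d, label) {
    tibble::tibble(role = label,
                   A_mean = mean(d$A), A_sd = stats::sd(d$A),
                   Ho_mean = mean(d$Ho), Ho_sd = stats::sd(d$Ho))
  }
  blocks <- list(summarize_block(per, "all"))
  for (r in unique(per$role)) {
    blocks <- c(blocks, list(summarize_block(per[per$role == r, ], r)))
  }
  list(per_locus = per, panel = dplyr::bind_rows(blocks))
}
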