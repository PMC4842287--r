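#' Construct a mapped, genotyped population
#'
#' The central container of the package: a set of individuals belonging to the
#' cohorts `father` (candidate pollen donor), `mother` (seed tree, also a
#' pollen candidate) and `offspring` (open-pollinated seedling with a known
#' mother), together with their diploid multilocus genotypes and planar
#' coordinates in meters.
#'
#' Genotypes are stored as an integer matrix with two columns per locus
#' (`<locus>_1`, `<locus>_2`); allele labels are integers (typically fragment
#' sizes). A missing genotype at a locus is encoded as `NA` in both columns.
#' The allele pair is unordered; pairs are stored sorted so that equal
#' genotypes compare equal.
#'
#' @param ind data.frame with columns `id`, `cohort`, `mother_id`, `x`, `y`.
#'   `mother_id` is `NA` for adults; `x`/`y` may be `NA` for offspring only.
#' @param geno integer matrix, one row per individual (same order as `ind`),
#'   two columns per locus named `<locus>_1`/`<locus>_2`.
#' @param loci character vector of locus names.
#' @param require_coords if `TRUE` (default), adults must be mapped; set to
#'   `FALSE` for genotypes-only imports (e.g. GenePop), which then support no
#'   spatial analysis until coordinates are attached.
#' @return An object of class `pollen_pop` with elements `ind`, `geno`, `loci`.
#' @export
pollen_pop <- function(ind, geno, loci = NULL, require_coords = TRUE) {
  stopifnot(is.data.frame(ind), is.matrix(geno), nrow(ind) == nrow(geno))
  need <- c("id", "cohort", "mother_id", "x", "y")
  miss <- setdiff(need, names(ind))
  if (length(miss)) stop("ind is missing columns: ", paste(miss, collapse = ", "))
  ind$id <- as.character(ind$id)
  ind$cohort <- as.character(ind$cohort)
  ind$mother_id <- as.character(ind$mother_id)
  if (anyDuplicated(ind$id)) {
    stop("duplicate id: ", paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(ind$cohort), c("father", "mother", "offspring"))
  if (length(bad)) stop("unknown cohort: ", paste(bad, collapse = ", "))
  if (is.null(loci)) {
    loci <- unique(sub("_[12]$", "", colnames(geno)))
  }
  if (ncol(geno) != 2L * length(loci)) {
    stop("geno must have two columns per locus")
  }
  colnames(geno) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  storage.mode(geno) <- "integer"
  # offspring must point at a mother; adults must be mapped
  off <- ind$cohort == "offspring"
  if (any(off & (is.na(ind$mother_id) | ind$mother_id == ""))) {
    stop("missing mother link for offspring: ",
         paste(ind$id[off & (is.na(ind$mother_id) | ind$mother_id == "")], collapse = ", "))
  }
  mothers <- ind$id[ind$cohort == "mother"]
  orphan <- off & !(ind$mother_id %in% mothers)
  if (any(orphan)) {
    stop("offspring reference unknown mothers: ",
         paste(ind$id[orphan], collapse = ", "))
  }
  adult <- ind$cohort %in% c("father", "mother")
  if (require_coords && any(adult & (is.na(ind$x) | is.na(ind$y)))) {
    stop("coordinate missing for adult: ",
         paste(ind$id[adult & (is.na(ind$x) | is.na(ind$y))], collapse = ", "))
  }
  # canonicalize unordered pairs: sort each pair, sweep half-missing to NA
  for (l in seq_along(loci)) {
    j <- 2L * l - 1L
    a <- geno[, j]; b <- geno[, j + 1L]
    half <- xor(is.na(a), is.na(b))
    a[half] <- NA_integer_; b[half] <- NA_integer_
    lo <- pmin(a, b); hi <- pmax(a, b)
    geno[, j] <- lo; geno[, j + 1L] <- hi
  }
  rownames(geno) <- ind$id
  structure(list(ind = ind, geno = geno, loci = loci), class = "pollen_pop")
}

#' @export
print.pollen_pop <- function(x, ...) {
  tab <- table(factor(x$ind$cohort, c("father", "mother", "offspring")))
  cat("<pollen_pop> ", nrow(x$ind), " individuals (",
      tab[["father"]], " candidate fathers, ", tab[["mother"]], " mothers, ",
      tab[["offspring"]], " offspring), ", length(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Number of individuals in a cohort
#'
#' @param pop a `pollen_pop`.
#' @param cohort one or more of `"father"`, `"mother"`, `"offspring"`,
#'   or `"adult"` (= father + mother). `NULL` selects everyone.
#' @return Logical vector selecting the rows of `pop$ind`.
#' @export
cohort_mask <- function(pop, cohort = NULL) {
  if (is.null(cohort)) return(rep(TRUE, nrow(pop$ind)))
  cohort <- unique(unlist(lapply(cohort, function(co)
    if (co == "adult") c("father", "mother") else co)))
  bad <- setdiff(cohort, c("father", "mother", "offspring"))
  if (length(bad)) stop("unknown cohort: ", paste(bad, collapse = ", "))
  pop$ind$cohort %in% cohort
}

#' Pairwise Euclidean distances between mapped individuals
#'
#' @inheritParams cohort_mask
#' @return Symmetric matrix of distances in meters, dimnames = ids.
#' @export
pop_distances <- function(pop, cohort = "adult") {
  m <- cohort_mask(pop, cohort)
  xy <- as.matrix(pop$ind[m, c("x", "y")])
  if (anyNA(xy)) stop("cannot compute distances: unmapped individuals selected")
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(pop$ind$id[m], pop$ind$id[m])
  d
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed over non-missing gene copies only; `n_copies`
#' records the number of copies actually counted per locus.
#'
#' @inheritParams cohort_mask
#' @return An object of class `allele_freqs`: a list with one element per
#'   locus, each a list with `freq` (named numeric, sums to 1) and `n_copies`.
#' @export
allele_frequencies <- function(pop, cohort = NULL) {
  m <- cohort_mask(pop, cohort)
  if (!any(m)) stop("empty cohort selection")
  out <- lapply(seq_along(pop$loci), function(l) {
    j <- 2L * l - 1L
    copies <- c(pop$geno[m, j], pop$geno[m, j + 1L])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0L) {
      stop("locus ", pop$loci[l], " has zero non-missing copies in selection")
    }
    tab <- table(copies)
    list(freq = as.numeric(tab) / length(copies),
         alleles = as.integer(names(tab)),
         n_copies = length(copies))
  })
  names(out) <- pop$loci
  for (l in seq_along(out)) names(out[[l]]$freq) <- out[[l]]$alleles
  structure(out, class = "allele_freqs")
}

#' Read a population from genotype and coordinate tables
#'
#' `genotypes.csv` has columns `id,cohort,mother_id,<locus>_1,<locus>_2,...`
#' with empty cells for missing data and `cohort` in
#' `{father, mother, offspring}`. `coords.csv` has columns `id,x,y` (meters).
#'
#' @param genotype_file,coords_file paths to CSV files. `coords_file` may be
#'   `NULL` for a genotypes-only population (no spatial analysis possible).
#' @return A validated [pollen_pop()].
#' @export
read_population <- function(genotype_file, coords_file = NULL) {
  g <- utils::read.csv(genotype_file, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "cohort", "mother_id")
  if (!all(need %in% names(g))) {
    stop("genotype table must have columns id, cohort, mother_id")
  }
  acols <- setdiff(names(g), need)
  if (length(acols) == 0L || length(acols) %% 2L != 0L) {
    stop("genotype table needs paired <locus>_1/<locus>_2 columns")
  }
  loci <- unique(sub("_[12]$", "", acols))
  if (!identical(paste0(rep(loci, each = 2), c("_1", "_2")), acols)) {
    stop("locus columns must come in adjacent _1/_2 pairs")
  }
  geno <- matrix(NA_integer_, nrow(g), length(acols),
                 dimnames = list(NULL, acols))
  for (j in seq_along(acols)) {
    v <- g[[acols[j]]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.integer(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      stop("allele not parseable as integer at ", acols[j], ": ",
           paste(unique(v[bad]), collapse = ", "))
    }
    geno[, j] <- num
  }
  ind <- data.frame(id = g$id, cohort = g$cohort,
                    mother_id = ifelse(g$mother_id == "", NA, g$mother_id),
                    x = NA_real_, y = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(coords_file)) {
    xy <- utils::read.csv(coords_file, stringsAsFactors = FALSE)
    if (!all(c("id", "x", "y") %in% names(xy))) {
      stop("coordinate table must have columns id, x, y")
    }
    i <- match(ind$id, as.character(xy$id))
    ind$x <- as.numeric(xy$x[i])
    ind$y <- as.numeric(xy$y[i])
  }
  pollen_pop(ind, geno, loci, require_coords = !is.null(coords_file))
}

#' Write a population to genotype and coordinate tables
#'
#' Individuals are written in canonical order (fathers, mothers, offspring;
#' ids lexicographic within cohort) and allele pairs sorted ascending, so that
#' write/read round-trips are byte-stable.
#'
#' @param pop a `pollen_pop`.
#' @param genotype_file,coords_file output CSV paths (`coords_file` optional).
#' @return Invisibly, `pop` in canonical order.
#' @export
write_population <- function(pop, genotype_file, coords_file = NULL) {
  ord <- order(match(pop$ind$cohort, c("father", "mother", "offspring")),
               pop$ind$id, method = "radix")
  ind <- pop$ind[ord, , drop = FALSE]
  geno <- pop$geno[ord, , drop = FALSE]
  g <- data.frame(id = ind$id, cohort = ind$cohort,
                  mother_id = ifelse(is.na(ind$mother_id), "", ind$mother_id),
                  stringsAsFactors = FALSE)
  for (j in seq_len(ncol(geno))) g[[colnames(geno)[j]]] <- geno[, j]
  gg <- g
  gg[is.na(gg)] <- ""
  utils::write.csv(gg, genotype_file, row.names = FALSE, quote = FALSE)
  if (!is.null(coords_file)) {
    ad <- ind$cohort %in% c("father", "mother") | !(is.na(ind$x) | is.na(ind$y))
    utils::write.csv(data.frame(id = ind$id[ad], x = ind$x[ad], y = ind$y[ad]),
                     coords_file, row.names = FALSE, quote = FALSE)
  }
  invisible(pollen_pop(ind, geno, pop$loci))
}

#' Project geodetic coordinates to local planar meters
#'
#' Equirectangular projection about the centroid: adequate for stands of
#' sub-kilometer extent, where Earth curvature is negligible relative to
#' GPS error.
#'
#' @param lat,lon numeric vectors in decimal degrees.
#' @return data.frame with `x`, `y` in meters, centered on the centroid.
#' @export
project_latlon <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  R <- 6371008.8
  lat0 <- mean(lat) * pi / 180
  lon0 <- mean(lon) * pi / 180
  data.frame(x = R * cos(lat0) * (lon * pi / 180 - lon0),
             y = R * (lat * pi / 180 - lat0))
}

#' Read a GenePop file
#'
#' Supports the 2- and 3-digit allele codings; `00`/`000` allele codes map to
#' missing. All samples are imported as cohort `father` (GenePop carries no
#' pedigree or coordinates); relabel cohorts afterwards if needed.
#'
#' @param path GenePop file.
#' @return A [pollen_pop()] without coordinates.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" | seq_along(lines) == 1L]
  if (length(lines) < 3L) stop("malformed GenePop file: too short")
  body <- lines[-1L]                      # first line is a title comment
  popidx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(popidx) == 0L) stop("malformed GenePop file: no POP line")
  hdr <- body[seq_len(popidx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(hdr, ",")))
  loci <- loci[loci != ""]
  if (length(loci) == 0L) stop("malformed GenePop file: no locus names")
  samp <- body[-seq_len(popidx[1L])]
  samp <- samp[!grepl("^\\s*pop\\s*$", samp, ignore.case = TRUE)]
  if (length(samp) == 0L) stop("malformed GenePop file: empty POP block")
  ids <- character(length(samp))
  geno <- matrix(NA_integer_, length(samp), 2L * length(loci))
  for (i in seq_along(samp)) {
    parts <- strsplit(samp[i], ",")[[1L]]
    if (length(parts) < 2L) stop("malformed GenePop sample line: ", samp[i])
    ids[i] <- trimws(parts[1L])
    codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(codes) != length(loci)) {
      stop("sample ", ids[i], " has ", length(codes), " genotypes for ",
           length(loci), " loci")
    }
    for (l in seq_along(codes)) {
      nc <- nchar(codes[l])
      if (!nc %in% c(4L, 6L) || grepl("\\D", codes[l])) {
        stop("bad GenePop genotype code '", codes[l], "' for sample ", ids[i])
      }
      w <- nc %/% 2L
      a <- as.integer(substr(codes[l], 1L, w))
      b <- as.integer(substr(codes[l], w + 1L, nc))
      if (a == 0L || b == 0L) { a <- NA_integer_; b <- NA_integer_ }
      geno[i, 2L * l - 1L] <- a
      geno[i, 2L * l] <- b
    }
  }
  colnames(geno) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  ind <- data.frame(id = ids, cohort = "father", mother_id = NA_character_,
                    x = NA_real_, y = NA_real_, stringsAsFactors = FALSE)
  pollen_pop(ind, geno, loci, require_coords = FALSE)
}

#' Write a GenePop file
#'
#' @param pop a `pollen_pop`.
#' @param path output path.
#' @param digits 2 or 3, the allele-code width.
#' @param title first (comment) line.
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(pop, path, digits = 3L, title = "polliflow export") {
  stopifnot(digits %in% c(2L, 3L))
  if (any(pop$geno >= 10^digits, na.rm = TRUE)) {
    stop("allele labels do not fit in ", digits, "-digit GenePop coding")
  }
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  out <- c(title, pop$loci, "POP")
  rows <- vapply(seq_len(nrow(pop$ind)), function(i) {
    codes <- vapply(seq_along(pop$loci), function(l) {
      paste0(fmt(pop$geno[i, 2L * l - 1L]), fmt(pop$geno[i, 2L * l]))
    }, character(1))
    paste0(pop$ind$id[i], " ,  ", paste(codes, collapse = " "))
  }, character(1))
  writeLines(c(out, rows), path)
  invisible(path)
}
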