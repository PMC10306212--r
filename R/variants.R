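#' Construct a table of variant keys
#'
#' A variant key identifies one biallelic variant by chromosome, 1-based
#' position, reference allele and a single alternate allele. Keys are the
#' join unit between the case cohort, the control summary and the
#' annotation table, so both sides must be normalized identically
#' (see [normalize_variants()]).
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions (integer).
#' @param ref Reference allele strings over \{A,C,G,T,N\}.
#' @param alt Single alternate allele strings (no commas).
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt` and a
#'   canonical `variant_id` ("chrom:pos:ref:alt").
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1")
  }
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("alt must contain a single allele; split multiallelic records first")
  }
  bad <- !grepl("^[ACGTN]+$", ref) | !grepl("^[ACGTN]+$", alt)
  if (any(bad)) {
    stop("alleles must be non-empty strings over {A,C,G,T,N}; offending: ",
         paste(utils::head(paste0(ref[bad], ">", alt[bad]), 3), collapse = ", "))
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    stringsAsFactors = FALSE
  )
}

#' Normalize variant keys by suffix/prefix trimming
#'
#' Reduces each (pos, ref, alt) pair to its minimal parsimonious
#' representation: shared trailing bases are trimmed while both alleles
#' retain length > 1, then shared leading bases are trimmed while both
#' alleles retain length > 1, incrementing the position by one per trimmed
#' leading base. This is the reference-free part of left-align/trim
#' normalization; it makes representation unique so case and control keys
#' match. The operation is idempotent and the identity on minimal keys.
#'
#' @param keys A data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (e.g. from [variant_key()]).
#' @return A data.frame of the same shape with normalized `pos`, `ref`,
#'   `alt` and recomputed `variant_id`.
#' @export
normalize_variants <- function(keys) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(keys)))
  ref <- toupper(keys$ref)
  alt <- toupper(keys$alt)
  pos <- as.integer(keys$pos)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared prefix, advancing the coordinate
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  variant_key(keys$chrom, pos, ref, alt)
}

#' Split multiallelic records into biallelic keys
#'
#' Expands rows whose `alt` holds a comma-separated allele list into one row
#' per alternate allele and normalizes every resulting key. Any additional
#' per-allele columns named in `per_allele` (comma-separated in step with
#' `alt`, e.g. control allele counts) are split alongside; all other columns
#' are recycled.
#'
#' @param tab A data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param per_allele Character vector of column names carrying one
#'   comma-separated value per alternate allele.
#' @return A data.frame of biallelic, normalized records with an
#'   `allele_index` column (1-based index of the allele in the original
#'   record, for genotype re-coding).
#' @export
split_multiallelic <- function(tab, per_allele = character()) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(tab)))
  alts <- strsplit(as.character(tab$alt), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(tab)), n_alt)
  out <- tab[idx, setdiff(names(tab), c("alt", per_allele)), drop = FALSE]
  out$alt <- unlist(alts)
  out$allele_index <- unlist(lapply(n_alt, seq_len))
  for (col in per_allele) {
    vals <- strsplit(as.character(tab[[col]]), ",", fixed = TRUE)
    if (!all(lengths(vals) == n_alt)) {
      stop("column '", col, "' does not have one value per alternate allele")
    }
    out[[col]] <- utils::type.convert(unlist(vals), as.is = TRUE)
  }
  norm <- normalize_variants(out)
  out$pos <- norm$pos
  out$ref <- norm$ref
  out$alt <- norm$alt
  out$variant_id <- norm$variant_id
  rownames(out) <- NULL
  out
}
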