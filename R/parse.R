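# Combined-orthology TSV dialect: 13 tab-separated columns, "#" comment
# lines, one header line, "|"-separated algorithm names, tri-state best
# flags {Yes, No, Yes_Adjusted}.

ORTHOLOGY_COLUMNS <- c(
  "gene1_id", "gene1_symbol", "gene1_taxon", "gene1_species_name",
  "gene2_id", "gene2_symbol", "gene2_taxon", "gene2_species_name",
  "algorithms", "algorithms_match", "out_of_algorithms",
  "is_best", "is_best_revised"
)

TRISTATE_TOKENS <- c("Yes", "No", "Yes_Adjusted")

#' Parse an NCBI-style taxon token
#'
#' Taxon columns carry tokens like `"NCBITaxon:9606"`; the integer after the
#' colon is the NCBI taxonomy id.
#'
#' @param token Character vector of taxon tokens.
#' @return Integer vector of taxon numbers.
#' @export
#' @examples
#' parse_taxon("NCBITaxon:9606")
parse_taxon <- function(token) {
  m <- regmatches(token, regexec("^[^:]+:([0-9]+)$", token))
  bad <- lengths(m) != 2L
  if (any(bad)) {
    stop("malformed taxon token: ", paste(token[bad], collapse = ", "))
  }
  as.integer(vapply(m, `[`, character(1), 2L))
}

#' Split a prefixed accession (curie) into namespace and local part
#'
#' Splits at the first colon, so local parts may themselves contain colons.
#' An accession without a colon yields an empty prefix; callers supply the
#' registered default for its source.
#'
#' @param ref Character vector of accessions.
#' @return A data.frame with columns `prefix` and `local`.
#' @export
#' @examples
#' split_curie(c("HGNC:5", "WB:WBGene00000001", "693363"))
split_curie <- function(ref) {
  if (any(!nzchar(ref))) stop("empty accession")
  pos <- regexpr(":", ref, fixed = TRUE)
  has <- pos > 0L
  data.frame(
    prefix = ifelse(has, substr(ref, 1L, pos - 1L), ""),
    local = ifelse(has, substr(ref, pos + 1L, nchar(ref)), ref),
    stringsAsFactors = FALSE
  )
}

#' Decode a tri-state best-score token
#'
#' `Yes` and `No` mark whether the pair is the top-ranked call for the source
#' gene; `Yes_Adjusted` marks a curated adjustment of that call.
#'
#' @param token Character vector over \{Yes, No, Yes_Adjusted\}.
#' @return data.frame with logical columns `best` and `adjusted`.
#' @export
parse_best_flag <- function(token) {
  bad <- !(token %in% TRISTATE_TOKENS)
  if (any(bad)) stop("unknown best-score token: ", paste(unique(token[bad]), collapse = ", "))
  data.frame(
    best = token != "No",
    adjusted = token == "Yes_Adjusted"
  )
}

#' Parse a combined-orthology TSV file
#'
#' Lines starting with `#` are comments/metadata; the first non-comment line
#' is the column header; every following line is one directed gene pair with
#' 13 tab-separated fields (see `RawOrthologyRow` semantics in the package
#' vignette). Column counts and tri-state tokens are validated with the
#' offending line number in the error.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of raw rows, one per data line, with columns
#'   `gene1_id, gene1_symbol, gene1_taxon, gene1_species_name, gene2_id,
#'   gene2_symbol, gene2_taxon, gene2_species_name, algorithms,
#'   algorithms_match, out_of_algorithms, is_best, is_best_revised`.
#' @export
parse_orthology_file <- function(path) {
  if (!file.exists(path)) stop("orthology file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  body <- lines[keep]
  body <- body[nzchar(body)]
  lineno <- lineno[nzchar(lines[keep])]
  if (length(body) == 0L) stop("orthology file has no header line")
  data <- body[-1L]
  lineno <- lineno[-1L]
  if (length(data) == 0L) {
    out <- data.frame(matrix(character(), 0L, 13L), stringsAsFactors = FALSE)
    names(out) <- ORTHOLOGY_COLUMNS
    out$algorithms_match <- integer()
    out$out_of_algorithms <- integer()
    return(out)
  }
  fields <- strsplit(data, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 13L)) {
    i <- which(nf != 13L)[1L]
    stop(sprintf("line %d: expected 13 tab-separated columns, got %d",
                 lineno[i], nf[i]))
  }
  mat <- matrix(unlist(fields), ncol = 13L, byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- ORTHOLOGY_COLUMNS

  am <- suppressWarnings(as.integer(out$algorithms_match))
  oa <- suppressWarnings(as.integer(out$out_of_algorithms))
  if (anyNA(am) || anyNA(oa)) {
    i <- which(is.na(am) | is.na(oa))[1L]
    stop(sprintf("line %d: non-numeric algorithm count", lineno[i]))
  }
  out$algorithms_match <- am
  out$out_of_algorithms <- oa
  for (col in c("is_best", "is_best_revised")) {
    bad <- !(out[[col]] %in% TRISTATE_TOKENS)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("line %d: unknown best-score token '%s'",
                   lineno[i], out[[col]][i]))
    }
  }
  out
}

#' Write raw orthology rows as a combined-orthology TSV
#'
#' Inverse of [parse_orthology_file()] for the 13-column dialect; used by the
#' fixture generator and for exporting subsets.
#'
#' @param rows data.frame with the 13 raw columns.
#' @param path Output path; if `NULL` the TSV text is returned invisibly.
#' @param comments Character vector of comment lines (written with `#`).
#' @return The TSV text, invisibly.
#' @export
write_orthology_file <- function(rows, path = NULL,
                                 comments = "generated fixture") {
  stopifnot(all(ORTHOLOGY_COLUMNS %in% names(rows)))
  rows <- rows[, ORTHOLOGY_COLUMNS, drop = FALSE]
  header <- paste(ORTHOLOGY_COLUMNS, collapse = "\t")
  body <- do.call(paste, c(lapply(rows, as.character), sep = "\t"))
  text <- c(paste0("# ", comments), header, body)
  if (!is.null(path)) writeLines(text, path)
  invisible(paste0(paste(text, collapse = "\n"), "\n"))
}
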