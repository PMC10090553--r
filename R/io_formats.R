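# I/O for the external representations the pipeline touches: delimited
# numeric matrices (genes x samples), GMT gene-set collections, plain
# symbol lists, and provenance-stamped result tables.

MISSING_TOKENS <- c("", "na", "nan")

#' Read a delimited numeric matrix of genes by samples
#'
#' Parses a CSV/TSV table whose first row and first column carry identifiers
#' and returns a numeric matrix in genes-as-rows orientation, regardless of
#' the orientation on disk. Gene symbols are canonicalized (uppercase,
#' whitespace-stripped); duplicate gene rows after canonicalization are an
#' integrity error, as are duplicate sample identifiers. Cells equal to
#' `""`, `"NA"` or `"NaN"` (any case) parse as missing; any other
#' non-numeric cell is a parse error naming the offending row and column.
#'
#' @param path Path to the file.
#' @param orientation `"genes-as-rows"` (default) if rows are genes, or
#'   `"genes-as-cols"` if the table on disk is transposed.
#' @param delimiter Field separator (default `","`).
#' @param strip_entrez Drop a trailing parenthesized token from gene
#'   identifiers (DepMap `"SYMBOL (ENTREZ)"` headers) before
#'   canonicalization.
#' @return Numeric matrix with genes as rownames and samples as colnames.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, orientation = c("genes-as-rows", "genes-as-cols"),
                        delimiter = ",", strip_entrez = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_validation("no such file: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "\"",
                           na.strings = character(0),
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_parse("matrix file needs an identifier column ",
                                 "plus at least one data column: ", path)
  ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(body) <- ids

  if (orientation == "genes-as-cols") body <- t(body)

  genes <- canonicalize_symbols(rownames(body), strip_entrez = strip_entrez)
  samples <- trimws(colnames(body))
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop_integrity("duplicate gene identifiers after canonicalization: ",
                   paste(unique(dup), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop_integrity("duplicate sample identifiers: ",
                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }

  vals <- suppressWarnings(as.numeric(body))
  is_missing_token <- tolower(trimws(body)) %in% MISSING_TOKENS
  bad <- which(is.na(vals) & !is_missing_token)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(body)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(body)) + 1L
    stop_parse("malformed numeric cell at row '", genes[i], "', column '",
               samples[j], "': \"", body[bad[1L]], "\"")
  }
  vals[is_missing_token] <- NA_real_
  m <- matrix(vals, nrow = nrow(body), dimnames = list(genes, samples))
  validate_matrix_table(m)
  m
}

#' Write a genes-by-samples matrix to a delimited file
#'
#' Values are written with 17 significant digits so that
#' `read_matrix(write_matrix(m))` reproduces `m` exactly; missing cells are
#' written as `"NA"`.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param delimiter Field separator (default `","`).
#' @param id_header Name for the identifier column (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = ",", id_header = "gene") {
  validate_matrix_table(m)
  txt <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m))
  txt[is.na(m)] <- "NA"
  lines <- c(
    paste(c(id_header, colnames(m)), collapse = delimiter),
    paste(rownames(m), apply(txt, 1L, paste, collapse = delimiter),
          sep = delimiter)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write matrix to: ", path)
  invisible(path)
}

#' Validate a genes-by-samples matrix
#'
#' Checks the container invariants: numeric matrix, unique non-empty row and
#' column identifiers, and no infinite values (missing `NA` is allowed).
#'
#' @param m Object to validate.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_matrix_table <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_validation("matrix table must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_validation("matrix table needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop_integrity("duplicate gene rownames")
  if (anyDuplicated(colnames(m))) stop_integrity("duplicate sample colnames")
  if (any(is.infinite(m))) {
    stop_validation("matrix table contains infinite values")
  }
  invisible(m)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name TAB description TAB member TAB member ...` (the MSigDB
#' interchange format). Member symbols are canonicalized; duplicates within a
#' set are collapsed keeping the first occurrence.
#'
#' @param path Path to the GMT file.
#' @return An object of class `"gene_set_collection"`: a list with `sets`
#'   (named list of character member vectors) and `descriptions` (named
#'   character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop_parse("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  }
  names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names)) {
    stop_integrity("duplicate gene-set names: ",
                   paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    members <- canonicalize_symbols(f[-(1:2)])
    members <- members[nzchar(members)]
    members[!duplicated(members)]
  })
  names(sets) <- names
  descriptions <- vapply(fields, `[[`, "", 2L)
  names(descriptions) <- names
  gene_set_collection(sets, descriptions)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member symbols
#'   (canonicalized on construction).
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `"gene_set_collection"` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || !all(nzchar(names(sets)))) {
    stop_validation("sets must be a named list of member vectors")
  }
  if (anyDuplicated(names(sets))) stop_integrity("duplicate gene-set names")
  sets <- lapply(sets, function(s) {
    s <- canonicalize_symbols(s)
    s <- s[nzchar(s)]
    s[!duplicated(s)]
  })
  if (any(lengths(sets) == 0L)) {
    stop_validation("every gene set must have at least one member")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x$sets), "sets;",
      "member counts:", paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection to GMT
#'
#' @param collection A `"gene_set_collection"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain symbol list
#'
#' One symbol per line; `#` comments and blank lines are skipped. Symbols are
#' canonicalized and de-duplicated preserving first appearance.
#'
#' @param path Path to the list file.
#' @return Character vector of unique canonical symbols.
#' @export
read_symbol_list <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  syms <- canonicalize_symbols(lines)
  syms <- syms[nzchar(syms)]
  syms <- syms[!duplicated(syms)]
  if (!length(syms)) stop_validation("symbol list is empty: ", path)
  syms
}

#' Write a result table as TSV with a provenance header
#'
#' Result tables carry a `#`-prefixed comment block (package version, seed,
#' parameter hash) ahead of the header line, so every output records how it
#' was produced.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param provenance Named list of values recorded in the comment block.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, provenance = list()) {
  provenance <- c(list(tool = paste0("codepnet ",
                                     as.character(utils::packageVersion("codepnet")))),
                  provenance)
  header <- vapply(names(provenance), function(k) {
    paste0("# ", k, ": ", paste(format(provenance[[k]]), collapse = " "))
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame; the provenance block is attached as
#'   `attr(x, "provenance")` (character vector of comment lines).
#' @export
read_result_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prov <- lines[startsWith(lines, "#")]
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}
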