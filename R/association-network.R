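#' Build a disease-microbe association network
#'
#' An association network is the labelled binary adjacency matrix `A`
#' (diseases in rows, microbes in columns) together with its label lists:
#' `A[i, j] = 1` when disease `i` has a curated association with microbe `j`,
#' 0 otherwise. It is the single input every other function in the package
#' consumes. Duplicate edges collapse to a single 1; labels keep their
#' first-appearance order so that results are reproducible from the same
#' input without any implicit re-sorting.
#'
#' @param x A data frame whose first two columns are disease and microbe
#'   labels (one row per curated association), or a binary matrix with
#'   row and column names (diseases x microbes).
#' @param ... Unused.
#' @return An object of class `assoc_network`: a list with elements
#'   `A` (binary matrix with dimnames), `diseases`, `microbes`,
#'   `rows_read` and `duplicates_removed`.
#' @examples
#' edges <- tibble::tibble(
#'   disease = c("asthma", "asthma", "colitis"),
#'   microbe = c("Prevotella", "Haemophilus", "Prevotella")
#' )
#' net <- association_network(edges)
#' glance(net)
#' @export
association_network <- function(x, ...) UseMethod("association_network")

#' @rdname association_network
#' @export
association_network.data.frame <- function(x, ...) {
  if (ncol(x) < 2L) {
    stop_contract("edge table must have at least two columns (disease, microbe)")
  }
  disease <- trimws(as.character(x[[1L]]))
  microbe <- trimws(as.character(x[[2L]]))
  if (length(disease) < 1L) stop_input("edge table has no rows")
  bad <- which(disease == "" | microbe == "")
  if (length(bad)) {
    stop_parse(sprintf("empty disease or microbe label in edge row %d", bad[1L]))
  }
  diseases <- unique(disease)
  microbes <- unique(microbe)
  A <- matrix(0, length(diseases), length(microbes),
              dimnames = list(diseases, microbes))
  A[cbind(match(disease, diseases), match(microbe, microbes))] <- 1
  new_assoc_network(A,
                    rows_read = length(disease),
                    duplicates_removed = length(disease) - sum(A))
}

#' @rdname association_network
#' @export
association_network.matrix <- function(x, ...) {
  check_binary_matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("d%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("m%03d", seq_len(ncol(x)))
  new_assoc_network(x, rows_read = sum(x), duplicates_removed = 0L)
}

new_assoc_network <- function(A, rows_read, duplicates_removed) {
  storage.mode(A) <- "double"
  diseases <- rownames(A)
  microbes <- colnames(A)
  if (anyDuplicated(diseases)) stop_contract("disease labels must be pairwise distinct")
  if (anyDuplicated(microbes)) stop_contract("microbe labels must be pairwise distinct")
  structure(
    list(A = A, diseases = diseases, microbes = microbes,
         rows_read = as.integer(rows_read),
         duplicates_removed = as.integer(duplicates_removed)),
    class = "assoc_network"
  )
}

#' Read a disease-microbe edge list from a TSV file
#'
#' Expects two tab-separated columns (disease, microbe), UTF-8, one row per
#' association. Lines starting with `#` are ignored; duplicate pairs are
#' collapsed. Extra columns beyond the first two are ignored, matching
#' HMDAD-style exports that carry evidence columns.
#'
#' @param path Path to the TSV file.
#' @param header Logical; `TRUE` when the first non-comment line is a header
#'   row to be skipped.
#' @return An [association_network()] object.
#' @export
read_association_edgelist <- function(path, header = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input(sprintf("input file not found: %s", path))
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(raw), "#") & nzchar(trimws(raw))
  line_no <- which(keep)
  rows <- raw[keep]
  if (isTRUE(header)) {
    rows <- rows[-1L]
    line_no <- line_no[-1L]
  }
  if (length(rows) == 0L) stop_input(sprintf("no data rows in %s", path))
  fields <- strsplit(rows, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) {
    stop_parse(sprintf("line %d of %s has fewer than 2 tab-separated columns",
                       line_no[short[1L]], path))
  }
  edges <- tibble(
    disease = vapply(fields, `[[`, character(1), 1L),
    microbe = vapply(fields, `[[`, character(1), 2L)
  )
  association_network(edges)
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf(
    "<assoc_network> %d diseases x %d microbes, %d known associations (density %.3f)\n",
    length(x$diseases), length(x$microbes), sum(x$A), mean(x$A)
  ))
  if (x$duplicates_removed > 0) {
    cat(sprintf("  (%d rows read, %d duplicate pairs removed)\n",
                x$rows_read, x$duplicates_removed))
  }
  invisible(x)
}

#' Tidy an association network into an edge table
#'
#' @param x An `assoc_network`.
#' @param ... Unused.
#' @return A tibble with columns `disease`, `microbe`, one row per known
#'   association, in row-major matrix order.
#' @method tidy assoc_network
#' @export
tidy.assoc_network <- function(x, ...) {
  idx <- which(t(x$A) == 1)
  m <- (idx - 1L) %% length(x$microbes) + 1L
  d <- (idx - 1L) %/% length(x$microbes) + 1L
  tibble(disease = x$diseases[d], microbe = x$microbes[m])
}

#' One-row summary of an association network
#'
#' @param x An `assoc_network`.
#' @param ... Unused.
#' @method glance assoc_network
#' @export
glance.assoc_network <- function(x, ...) {
  tibble(
    n_diseases = length(x$diseases),
    n_microbes = length(x$microbes),
    n_associations = as.integer(sum(x$A)),
    density = mean(x$A),
    rows_read = x$rows_read,
    duplicates_removed = x$duplicates_removed
  )
}

#' Write a ranked score table as TSV
#'
#' Produces a long-format table with columns `disease`, `microbe`, `score`,
#' `known`, sorted by descending score within each disease (diseases in
#' network order). Ties are broken by microbe label so the output is fully
#' deterministic.
#'
#' @param net The `assoc_network` the scores were computed for.
#' @param scores An `ncp_scores` object from [predict.assoc_network()], or a
#'   bare numeric matrix with matching dimensions.
#' @param path Output file path (written atomically).
#' @param digits Number of decimal places for the printed scores.
#' @return Invisibly, the tibble that was written.
#' @export
write_score_table <- function(net, scores, path, digits = 6) {
  S <- if (inherits(scores, "ncp_scores")) scores$S else scores
  if (!is.matrix(S) || nrow(S) != length(net$diseases) ||
      ncol(S) != length(net$microbes)) {
    stop_contract("score matrix dimensions do not match the association network")
  }
  tab <- score_table(net, S)
  out <- tab
  out$score <- sprintf(paste0("%.", digits, "f"), out$score)
  write_atomic(function(tmp) readr::write_tsv(out, tmp, progress = FALSE), path)
  invisible(tab)
}

# long-format ranked score tibble shared by tidy.ncp_scores / write_score_table
score_table <- function(net, S) {
  tab <- tibble(
    disease = rep(net$diseases, times = length(net$microbes)),
    microbe = rep(net$microbes, each = length(net$diseases)),
    score = as.vector(S),
    known = as.integer(as.vector(net$A) == 1)
  )
  dorder <- match(tab$disease, net$diseases)
  tab[order(dorder, -tab$score, tab$microbe), ]
}

#' Write an association network back out as a two-column edge list
#'
#' Inverse of [read_association_edgelist()] for networks without isolated
#' entities: reading the written file reconstructs the adjacency matrix
#' bit for bit (isolated diseases or microbes have no edges to carry them).
#'
#' @param net An `assoc_network`.
#' @param path Output TSV path (written atomically).
#' @return Invisibly, `path`.
#' @export
write_association_edgelist <- function(net, path) {
  edges <- tidy(net)
  write_atomic(function(tmp) {
    readr::write_tsv(edges, tmp, col_names = FALSE, progress = FALSE)
  }, path)
  invisible(path)
}

#' Read back a score table written by [write_score_table()]
#'
#' @param path Path to a 4-column TSV (disease, microbe, score, known).
#' @return A tibble with those columns.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("input file not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    disease = readr::col_character(),
    microbe = readr::col_character(),
    score = readr::col_double(),
    known = readr::col_integer()
  ), progress = FALSE)
}
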