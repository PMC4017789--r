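#' Read protein GO annotations from a GAF 2.x file
#'
#' Loads a Gene Association File into a named list mapping protein id
#' (column 2) to the set of directly assigned GO term ids (column 5).
#' Rows whose qualifier contains `NOT` are dropped, duplicate
#' (protein, term) pairs are collapsed, and assignments with an excluded
#' evidence code are removed. A protein whose every assignment is excluded
#' is absent from the result entirely, mirroring the common practice of
#' excluding proteins annotated only by electronic (IEA) evidence.
#'
#' @param path path to a GAF 2.x tab-separated file (`!` comments allowed).
#' @param exclude_evidence character vector of evidence codes to drop;
#'   default `"IEA"`. Use `character(0)` to keep everything.
#' @return named list: protein id -> character vector of GO term ids.
#' @export
read_gaf <- function(path, exclude_evidence = "IEA") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L)) {
    bad <- which(nf < 7L)[1L]
    stop_domfun("GAF parse error: line ", bad, " has ", nf[bad],
                " columns (at least 7 required)")
  }
  prot <- vapply(fields, `[[`, character(1), 2L)
  qual <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evid <- vapply(fields, `[[`, character(1), 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual) & !(evid %in% exclude_evidence)
  prot <- prot[keep]; term <- term[keep]
  if (!length(prot)) return(stats::setNames(list(), character(0)))
  out <- lapply(split(term, prot), unique)
  out[order(names(out))]
}

#' Write an annotation set as a minimal GAF 2.1 file
#'
#' @param annotations named list: protein -> GO term ids.
#' @param path output path.
#' @param dag optional [go_dag] used to fill the aspect column (F/P/C).
#' @param evidence evidence code written for every row.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, dag = NULL, evidence = "EXP") {
  check_named_sets(annotations, "annotations")
  aspect <- function(term) {
    if (is.null(dag)) return("F")
    switch(dag$namespace[[term]] %||% "molecular_function",
           molecular_function = "F", biological_process = "P",
           cellular_component = "C", "F")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  for (p in names(annotations)) {
    for (g in annotations[[p]]) {
      writeLines(paste("DB", p, p, "", g, "REF:0000001", evidence, "",
                       aspect(g), "", "", "protein", "taxon:0000", "20260101",
                       "domfun", "", "", sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read protein domain compositions from a TSV file
#'
#' Expects the protein id in column 1 and its domain accessions after it,
#' either comma-separated in column 2 or spread over further tab-separated
#' columns. Repeated occurrences of a domain within one protein are collapsed
#' to a set: the downstream transfer rule takes a maximum over resident
#' domains, so multiplicity cannot change any score. Lines starting with `#`
#' are ignored; rows with an empty domain field are skipped with a warning.
#'
#' @param path path to the TSV file.
#' @return named list: protein id -> character vector of domain accessions.
#' @export
read_domains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    doms <- unlist(strsplit(parts[-1L], ",", fixed = TRUE), use.names = FALSE)
    doms <- unique(trimws(doms))
    doms <- doms[nzchar(doms)]
    if (!length(doms)) { skipped <- skipped + 1L; next }
    out[[parts[[1L]]]] <- unique(c(out[[parts[[1L]]]], doms))
  }
  if (skipped > 0L)
    warning(skipped, " row(s) with empty domain field skipped", call. = FALSE)
  out[order(names(out))]
}

#' Write domain compositions as TSV
#'
#' @param domains named list: protein -> domain accessions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path) {
  check_named_sets(domains, "domains")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#protein\tdomains", con)
  for (p in names(domains))
    writeLines(paste0(p, "\t", paste(domains[[p]], collapse = ",")), con)
  invisible(path)
}

#' Read an unweighted domain-to-term mapping in pfam2go format
#'
#' Parses lines of the form
#' `Pfam:PF00001 7tm_1 > GO:G protein-coupled receptor ; GO:0007165`,
#' returning one (domain, term) pair per line with duplicates collapsed.
#' Lines starting with `!` are comments.
#'
#' @param path path to a pfam2go-style text file.
#' @return data.frame with character columns `domain` and `term`.
#' @export
read_pfam2go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  doms <- character(length(lines)); terms <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    sep <- regexpr(";\\s*GO:\\d{7}\\s*$", ln)
    if (sep < 0L)
      stop_domfun("pfam2go parse error at line ", i,
                  ": missing '; GO:NNNNNNN' separator")
    terms[[i]] <- regmatches(ln, regexpr("GO:\\d{7}\\s*$", ln))
    head_part <- trimws(substr(ln, 1L, sep - 1L))
    dom <- strsplit(head_part, "\\s+")[[1L]][[1L]]
    doms[[i]] <- sub("^Pfam:", "", dom)
  }
  unique(data.frame(domain = doms, term = trimws(terms),
                    stringsAsFactors = FALSE))
}

#' Write and read prediction sets
#'
#' Predictions are serialized as a tab-separated table with a header line and
#' columns protein, term, score; scores are printed with 6 decimals so the
#' round trip is lossless at that precision. Scores must lie in \[0, 1\]
#' (they are root-normalized relevances).
#'
#' @param preds a [prediction_set].
#' @param path file path.
#' @return `write_predictions` returns `path` invisibly; `read_predictions`
#'   returns a [prediction_set].
#' @export
write_predictions <- function(preds, path) {
  stopifnot(inherits(preds, "prediction_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#namespace=", preds$namespace %||% "molecular_function"),
             con)
  writeLines("protein\tterm\tscore", con)
  for (p in names(preds$scores)) {
    sc <- preds$scores[[p]]
    if (any(sc < 0 | sc > 1))
      stop_domfun("refusing to write scores outside [0,1] for protein ", p)
    if (length(sc))
      writeLines(paste(p, names(sc), sprintf("%.6f", sc), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ns <- "molecular_function"
  meta <- grep("^#namespace=", lines, value = TRUE)
  if (length(meta)) ns <- sub("^#namespace=", "", meta[[1L]])
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) && lines[[1L]] == "protein\tterm\tscore")
    lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(prediction_set(stats::setNames(list(), character(0)), ns))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  prot <- vapply(fields, `[[`, character(1), 1L)
  term <- vapply(fields, `[[`, character(1), 2L)
  score <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  scores <- lapply(split(seq_along(prot), prot),
                   function(i) stats::setNames(score[i], term[i]))
  prediction_set(scores[order(names(scores))], ns)
}

#' Write and read weighted domain-to-term mappings
#'
#' Mapping TSV columns: domain, term, score, method, extension.
#'
#' @param map a `domain_go_map` (see [relevance_scp()]).
#' @param path file path.
#' @return `write_mapping` returns `path` invisibly; `read_mapping` a
#'   `domain_go_map`.
#' @export
write_mapping <- function(map, path) {
  stopifnot(inherits(map, "domain_go_map"))
  df <- data.frame(domain = map$domain, term = map$term,
                   score = sprintf("%.10g", map$score),
                   method = attr(map, "method"),
                   extension = attr(map, "extension"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "character", "character"))
  new_domain_go_map(df$domain, df$term, df$score,
                    method = if (nrow(df)) df$method[1L] else "scp",
                    extension = if (nrow(df)) df$extension[1L] else "none")
}
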