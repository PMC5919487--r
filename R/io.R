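# Plain-text readers/writers: edge lists (two whitespace-separated label
# columns, '#' comments), modification streams (op, label, label),
# count matrices, ranked lists, gold standards, sparse deltas, JSON
# sidecars. All round-trip losslessly on the test fixtures.

read_token_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], numbers = which(keep))
}

#' Read an edge list
#'
#' Two whitespace-separated node-label columns; lines starting with `#` are
#' comments. Self-loops and malformed lines are parse errors naming the line
#' number. Duplicate edges are collapsed.
#'
#' @param path file path.
#' @return A [gd_graph()] with labels taken from the file (sorted).
#' @export
read_edge_list <- function(path) {
  tl <- read_token_lines(path)
  if (!length(tl$lines)) return(gd_graph(0L))
  parts <- strsplit(trimws(tl$lines), "\\s+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 2L)
      stop("read_edge_list: line ", tl$numbers[i], ": expected two columns")
    if (parts[[i]][1L] == parts[[i]][2L])
      stop("read_edge_list: line ", tl$numbers[i], ": self-loop '",
           parts[[i]][1L], "'")
  }
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  labels <- sort(unique(c(a, b)))
  e <- unique(cbind(pmin(match(a, labels), match(b, labels)),
                    pmax(match(a, labels), match(b, labels))))
  gd_graph(length(labels), e, labels = labels)
}

#' Write an edge list
#' @param g a [gd_graph()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  e <- gd_edges(g)
  writeLines(c("# source target",
               sprintf("%s\t%s", g$labels[e[, 1L]], g$labels[e[, 2L]])), path)
  invisible(path)
}

#' Read a modification stream
#'
#' TSV with columns op (`+` or `-`), node label, node label.
#'
#' @param path file path.
#' @param labels node-label universe used to map labels to ids.
#' @return Data frame `op`, `u`, `v` (1-based ids into `labels`).
#' @export
read_modification_stream <- function(path, labels) {
  tl <- read_token_lines(path)
  if (!length(tl$lines))
    return(data.frame(op = character(0), u = integer(0), v = integer(0)))
  parts <- strsplit(trimws(tl$lines), "\\s+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L || !(p[1L] %in% c("+", "-")))
      stop("read_modification_stream: line ", tl$numbers[i],
           ": expected (op in {+,-}, node, node)")
    if (!(p[2L] %in% labels) || !(p[3L] %in% labels))
      stop("read_modification_stream: line ", tl$numbers[i],
           ": unknown node label")
  }
  data.frame(op = vapply(parts, `[`, "", 1L),
             u = match(vapply(parts, `[`, "", 2L), labels),
             v = match(vapply(parts, `[`, "", 3L), labels),
             stringsAsFactors = FALSE)
}

#' Write a modification stream
#' @param mods data frame `op`, `u`, `v` (ids).
#' @param labels node labels.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_modification_stream <- function(mods, labels, path) {
  writeLines(c("# op source target",
               if (NROW(mods)) sprintf("%s\t%s\t%s", mods$op,
                                       labels[mods$u], labels[mods$v])), path)
  invisible(path)
}

#' Write a count matrix and graphlet totals
#' @param cobj a `graphlet_counts` object.
#' @param prefix output path prefix; writes `<prefix>.counts.tsv` and
#'   `<prefix>.totals.tsv`.
#' @return The two paths, invisibly.
#' @export
write_counts <- function(cobj, prefix) {
  cpath <- paste0(prefix, ".counts.tsv")
  tpath <- paste0(prefix, ".totals.tsv")
  df <- data.frame(node = rownames(cobj$counts), cobj$counts,
                   check.names = FALSE)
  utils::write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(graphlet = names(cobj$totals),
                                count = as.numeric(cobj$totals)),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cpath, tpath))
}

#' Read a count matrix written by [write_counts()]
#' @param path the `.counts.tsv` path.
#' @return Matrix with node-label rownames and orbit colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Read a ranked interaction list
#'
#' TSV `source`, `target`, `score`. Directed records are canonicalised to
#' undirected pairs (best score kept) and the list is sorted by descending
#' score.
#'
#' @param path file path.
#' @return Data frame `source`, `target`, `score`.
#' @export
read_ranked_list <- function(path) {
  tl <- read_token_lines(path)
  parts <- strsplit(trimws(tl$lines), "\\s+")
  parts <- parts[!vapply(parts, function(p)
    identical(tolower(p[1L]), "source"), logical(1))]
  if (!length(parts))
    return(data.frame(source = character(0), target = character(0),
                      score = numeric(0)))
  bad <- vapply(parts, function(p)
    length(p) < 3L || is.na(suppressWarnings(as.numeric(p[3L]))), logical(1))
  if (any(bad))
    stop("read_ranked_list: malformed record (need source, target, ",
         "numeric score) at line ", tl$numbers[which(bad)[1L]])
  normalise_ranked(data.frame(
    source = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 2L),
    score = as.numeric(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE))
}

#' Write a ranked interaction list
#' @param ranked data frame `source`, `target`, `score`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  writeLines(c("source\ttarget\tscore",
               sprintf("%s\t%s\t%.10g", ranked$source, ranked$target,
                       ranked$score)), path)
  invisible(path)
}

#' Read a two-column gold-standard interaction list
#' @param path file path.
#' @return Data frame `source`, `target`.
#' @export
read_gold_standard <- function(path) {
  tl <- read_token_lines(path)
  parts <- strsplit(trimws(tl$lines), "\\s+")
  data.frame(source = vapply(parts, `[`, "", 1L),
             target = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

#' Write a sparse delta
#' @param d a `graphlet_delta`.
#' @param labels node labels.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_delta <- function(d, labels, path) {
  writeLines(c("# node orbit delta",
               if (nrow(d$delta)) sprintf("%s\t%d\t%d", labels[d$delta$node],
                                          d$delta$orbit,
                                          as.integer(d$delta$delta))), path)
  invisible(path)
}

# resolved-config sidecar: every command writes one next to its outputs
write_sidecar <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
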