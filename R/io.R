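# Edge-list input and JSON report output.

#' Read a directed graph from an edge-list file
#'
#' Parses a two-column (source, target) tab- or comma-separated file with
#' arbitrary string node labels; labels are mapped to dense integer ids in
#' first-appearance order. Duplicate rows are deduplicated with a message;
#' self-loops abort unless `dropSelfLoops` is set, in which case they are
#' dropped with a message.
#'
#' @param path path to the edge-list file.
#' @param sep field separator; guessed from the first line when `NULL`.
#' @param header does the file carry a header line?
#' @param dropSelfLoops drop self-loops instead of raising an error.
#' @return A [DirectedGraph-class].
#' @export
readEdgeList <- function(path, sep = NULL, header = FALSE, dropSelfLoops = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    if (length(first) == 0) stop("empty edge-list file: ", path)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  }
  df <- read.table(path, sep = sep, header = header,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list must have at least two columns")
  src <- df[[1]]; dst <- df[[2]]
  loops <- src == dst
  if (any(loops)) {
    if (!dropSelfLoops)
      stop(sum(loops), " self-loop(s) in edge list; use dropSelfLoops = TRUE")
    message("dropped ", sum(loops), " self-loop(s)")
    src <- src[!loops]; dst <- dst[!loops]
  }
  keys <- paste0(src, "\r", dst)
  dup <- duplicated(keys)
  if (any(dup)) {
    message("deduplicated ", sum(dup), " repeated edge(s)")
    src <- src[!dup]; dst <- dst[!dup]
  }
  labs <- unique(c(rbind(src, dst)))
  directedGraph(cbind(match(src, labs), match(dst, labs)),
                N = length(labs), labels = labs)
}

#' Write a graph as an edge-list TSV
#'
#' @param g a [DirectedGraph-class].
#' @param path output path.
#' @export
writeEdgeList <- function(g, path) {
  labs <- g@labels
  write.table(data.frame(from = labs[g@edges[, 1]], to = labs[g@edges[, 2]]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.SCHEMA_VERSION <- "1.0"

#' @noRd
.reportList <- function(report) {
  if (is(report, "SelectionReport")) {
    motifs <- report@motifs
    m <- multiplicities(motifs)
    list(schema = .SCHEMA_VERSION, type = "selection",
         bestModel = report@bestLabel,
         codelength = report@codelength,
         deltaLstar = report@deltaLstar,
         deltaLmotifs = if (is.na(report@deltaLmotifs)) NULL else report@deltaLmotifs,
         pBound = report@pBound,
         models = report@models,
         motifs = if (length(m) == 0) list() else
           lapply(names(m), function(id) list(id = id, multiplicity = m[[id]])),
         runCodelengths = report@runCodelengths)
  } else if (is(report, "HTResult")) {
    list(schema = .SCHEMA_VERSION, type = "hypothesis-testing",
         settings = report@settings, table = report@table)
  } else if (is(report, "MotifSummary")) {
    list(schema = .SCHEMA_VERSION, type = "motif-summary",
         means = as.list(report@means), baselines = as.list(report@baselines),
         perGraphlet = report@perGraphlet)
  } else if (is.list(report)) {
    c(list(schema = .SCHEMA_VERSION), report)
  } else stop("unsupported report type: ", class(report))
}

#' Write an analysis report as JSON
#'
#' Serializes a [SelectionReport-class], [HTResult-class],
#' [MotifSummary-class] or plain list to JSON with a schema version field.
#'
#' @param report the report object.
#' @param path output path.
#' @param config optional configuration echo (seeds, batch size, sizes)
#'   stored alongside the results.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, path, config = NULL) {
  x <- .reportList(report)
  if (!is.null(config)) x$config <- config
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a JSON report
#'
#' @param path path to a file written by [writeReport()].
#' @return The report as a list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
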