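# HTTP microservice: a database is opened once at startup and served over
# HTTP, so many queries reuse one in-memory index; a remote client mirrors
# local search() exactly.
#
# API (a documented convention of this artifact):
#   GET  /info                -> JSON service/database metadata
#   POST /search?type=...&... -> raw FASTA/FASTQ body; JSON response with a
#                                per-query list of hit objects
# Search query parameters: type (protein|dna|reads), min_kmatch, min_ratio,
# aln (0|1), matrix, gapopen, gapext, max_results, lambda, kparam, fields
# (comma-separated annotation fields). Errors return a JSON object with an
# "error" field and a 4xx status; the service stays up.

.parse_query_string <- function(qs) {
  if (is.null(qs) || qs == "" || qs == "?") return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p)
    httpuv::decodeURIComponent(if (length(p) > 1L) p[2L] else ""))
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  vals
}

.opts_from_params <- function(p) {
  g <- function(key, default) if (!is.null(p[[key]])) p[[key]] else default
  mr <- g("max_results", "10")
  search_options(
    min_kmatch = as.integer(g("min_kmatch", "10")),
    min_ratio = as.numeric(g("min_ratio", "0")),
    align = g("aln", "0") %in% c("1", "true", "TRUE"),
    matrix = g("matrix", "BLOSUM62"),
    gap_open = as.integer(g("gapopen", "11")),
    gap_extend = as.integer(g("gapext", "1")),
    max_results = if (tolower(mr) %in% c("inf", "all")) Inf
                  else as.numeric(mr),
    lambda = as.numeric(g("lambda", "0.267")),
    K = as.numeric(g("kparam", "0.041"))
  )
}

.opts_to_params <- function(opts, query_type, annotation_fields = NULL) {
  p <- c(
    type = query_type,
    min_kmatch = as.character(opts$min_kmatch),
    min_ratio = format(opts$min_ratio, digits = 17),
    aln = if (opts$align) "1" else "0",
    matrix = opts$matrix,
    gapopen = as.character(opts$gap_open),
    gapext = as.character(opts$gap_extend),
    max_results = if (is.finite(opts$max_results))
      as.character(opts$max_results) else "inf",
    lambda = format(opts$lambda, digits = 17),
    kparam = format(opts$K, digits = 17)
  )
  if (!is.null(annotation_fields))
    p <- c(p, fields = paste(annotation_fields, collapse = ","))
  paste(paste0(names(p), "=", vapply(p, curl::curl_escape, character(1))),
        collapse = "&")
}

.json_response <- function(body, status = 200L) {
  list(status = status,
       headers = list("Content-Type" = "application/json"),
       body = body)
}

.hits_payload <- function(hits) {
  by_query <- if (nrow(hits) > 0L)
    split(seq_len(nrow(hits)), factor(hits$query, levels = unique(hits$query)))
  else list()
  results <- lapply(names(by_query), function(q) {
    list(query = q,
         hits = hits[by_query[[q]], setdiff(names(hits), "query"),
                     drop = FALSE])
  })
  jsonlite::toJSON(
    list(columns = names(hits), results = results),
    dataframe = "rows", digits = NA, auto_unbox = TRUE, na = "null"
  )
}

.service_app <- function(db, started) {
  list(call = function(req) {
    tryCatch({
      path <- req$PATH_INFO
      method <- req$REQUEST_METHOD
      if (method == "GET" && path == "/info") {
        info <- list(
          name = basename(db$dir),
          n_proteins = db$meta$n_proteins,
          n_kmers = db$meta$n_kmers,
          n_combinations = db$meta$n_combinations,
          k = db$meta$k,
          format_version = db$meta$format_version,
          store_sequences = db$meta$store_sequences,
          uptime_s = as.numeric(difftime(Sys.time(), started, units = "secs"))
        )
        return(.json_response(jsonlite::toJSON(info, auto_unbox = TRUE)))
      }
      if (method == "POST" && path == "/search") {
        params <- .parse_query_string(req$QUERY_STRING)
        body_raw <- req$rook.input$read()
        body <- if (length(body_raw) > 0L) rawToChar(body_raw) else ""
        if (!grepl("\\S", body))
          return(.json_response(
            jsonlite::toJSON(list(error = "empty query body"),
                             auto_unbox = TRUE), status = 400L))
        query_type <- if (!is.null(params$type)) params$type else "protein"
        if (!query_type %in% c("protein", "dna", "reads"))
          return(.json_response(
            jsonlite::toJSON(list(error = paste0("unknown query type: ",
                                                 query_type)),
                             auto_unbox = TRUE), status = 400L))
        opts <- .opts_from_params(params)
        fields <- NULL
        if (!is.null(params$fields) && nzchar(params$fields))
          fields <- strsplit(params$fields, ",", fixed = TRUE)[[1L]]
        tmp <- tempfile(fileext = if (query_type == "reads") ".fastq"
                        else ".fasta")
        on.exit(unlink(tmp), add = TRUE)
        writeLines(body, tmp, sep = "")
        hits <- search(db, tmp, query_type, opts,
                       annotation_fields = fields)
        return(.json_response(.hits_payload(hits)))
      }
      .json_response(jsonlite::toJSON(list(error = "not found"),
                                      auto_unbox = TRUE), status = 404L)
    }, error = function(e) {
      .json_response(jsonlite::toJSON(list(error = conditionMessage(e)),
                                      auto_unbox = TRUE), status = 400L)
    })
  })
}

#' Serve a database over HTTP
#'
#' Opens the database once and answers `GET /info` and `POST /search`
#' requests against the in-memory index until interrupted (or until the
#' returned handle is stopped, in non-blocking mode). Malformed requests get
#' a structured JSON error and the service stays up.
#'
#' @param db_path database directory (see [build_database()]).
#' @param host bind address (default `"127.0.0.1"`).
#' @param port TCP port.
#' @param blocking run the event loop in this process (default `TRUE`); with
#'   `FALSE` the started server handle is returned and the caller drives the
#'   event loop (`httpuv::service()`) or stops it (`httpuv::stopServer()`).
#' @return (non-blocking mode) the httpuv server handle.
#' @export
serve <- function(db_path, host = "127.0.0.1", port = 8553L,
                  blocking = TRUE) {
  db <- open_database(db_path)   # corrupt/missing database fails here
  app <- .service_app(db, Sys.time())
  server <- httpuv::startServer(host, as.integer(port), app)
  if (!blocking) return(server)
  on.exit(httpuv::stopServer(server))
  message("serving ", db_path, " on http://", host, ":", port)
  while (TRUE) httpuv::service(250)
}

.http <- function(url, handle = curl::new_handle()) {
  res <- tryCatch(curl::curl_fetch_memory(url, handle = handle),
                  error = function(e)
                    stop("cannot reach service at ", url, ": ",
                         conditionMessage(e), call. = FALSE))
  body <- rawToChar(res$content)
  if (res$status_code >= 400L) {
    msg <- tryCatch(jsonlite::fromJSON(body)$error, error = function(e) body)
    stop("service error (HTTP ", res$status_code, "): ", msg, call. = FALSE)
  }
  body
}

#' Query service metadata
#'
#' @param url service base URL, e.g. `"http://127.0.0.1:8553"`.
#' @return named list mirroring the served database's metadata.
#' @export
client_info <- function(url) {
  jsonlite::fromJSON(.http(paste0(sub("/$", "", url), "/info")))
}

#' Search a remote database
#'
#' Sends a query file to a running service and returns the same hits
#' data.frame that [search()] would produce locally against the same
#' database and options (byte-identical after [write_tabular_hits()]
#' rendering).
#'
#' @param url service base URL.
#' @param query_path FASTA (protein/dna) or FASTQ (reads) query file.
#' @param query_type `"protein"`, `"dna"` or `"reads"`.
#' @param opts [search_options()].
#' @param annotation_fields annotation fields to attach (as in [search()]).
#' @return data.frame of ranked hits.
#' @export
client_search <- function(url, query_path,
                          query_type = c("protein", "dna", "reads"),
                          opts = search_options(),
                          annotation_fields = NULL) {
  query_type <- match.arg(query_type)
  opts <- .as_opts(opts)
  if (!file.exists(query_path))
    stop("no such file: ", query_path, call. = FALSE)
  body <- readChar(query_path, file.size(query_path), useBytes = TRUE)
  h <- curl::new_handle()
  curl::handle_setopt(h, customrequest = "POST", postfields = body)
  curl::handle_setheaders(h, "Content-Type" = "text/plain")
  qs <- .opts_to_params(opts, query_type, annotation_fields)
  resp <- .http(paste0(sub("/$", "", url), "/search?", qs), handle = h)
  .hits_from_payload(resp)
}

.hits_from_payload <- function(json) {
  parsed <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                               simplifyVector = TRUE)
  cols <- unlist(parsed$columns)
  pieces <- list()
  results <- parsed$results
  n_res <- if (is.data.frame(results)) nrow(results) else length(results)
  for (i in seq_len(n_res)) {
    r <- if (is.data.frame(results)) list(query = results$query[i],
                                          hits = results$hits[[i]])
         else results[[i]]
    h <- r$hits
    if (is.null(h) || NROW(h) == 0L) next
    h <- as.data.frame(h, stringsAsFactors = FALSE)
    h$query <- r$query
    pieces[[length(pieces) + 1L]] <- h[, cols, drop = FALSE]
  }
  if (length(pieces) == 0L) {
    out <- as.data.frame(
      stats::setNames(rep(list(logical(0)), length(cols)), cols))
    proto <- .empty_hits(align = all(c("raw_score", "bit_score") %in% cols),
                         dna = "frame" %in% cols)
    for (cc in intersect(names(proto), cols)) out[[cc]] <- proto[[cc]]
    return(out[, cols, drop = FALSE])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if ("target_pid" %in% cols) out$target_pid <- as.integer(out$target_pid)
  if ("shared_kmers" %in% cols)
    out$shared_kmers <- as.integer(out$shared_kmers)
  if ("target_length" %in% cols)
    out$target_length <- as.integer(out$target_length)
  for (cc in intersect(c("frame", "segment", "dna_start", "dna_end",
                         "raw_score", "q_start", "q_end", "t_start",
                         "t_end"), cols))
    out[[cc]] <- as.integer(out[[cc]])
  out
}
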