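# HTTP plugin protocol: a segmentation plugin is an HTTP endpoint that
# accepts a multipart/form-data POST whose "file" field holds an anonymized
# DICOM slice (plus text fields with slice metadata) and answers with an
# image/png binary mask of the same shape; all non-zero pixels are treated
# as 1 on receipt. Both sides are implemented here: a client (call_plugin)
# and a reference server (serve_plugins) exposing the built-in segmenters.

# --- multipart parsing ------------------------------------------------------

# Parse a multipart/form-data body. `boundary` may be NULL, in which case it
# is taken from the first line of the body. Returns list name -> raw value.
parse_multipart <- function(body, boundary = NULL) {
  if (is.null(boundary)) {
    eol <- grepRaw("\r\n", body, fixed = TRUE)
    if (length(eol) == 0L) stop("malformed multipart body", call. = FALSE)
    first <- rawToChar(body[1:(eol[1] - 1L)])
    if (!startsWith(first, "--")) stop("malformed multipart body", call. = FALSE)
    boundary <- substring(first, 3L)
  }
  delim <- charToRaw(paste0("--", boundary))
  hits <- grepRaw(delim, body, fixed = TRUE, all = TRUE)
  if (length(hits) < 2L) stop("malformed multipart body", call. = FALSE)
  parts <- list()
  for (i in seq_len(length(hits) - 1L)) {
    start <- hits[i] + length(delim)
    # skip the CRLF after the delimiter
    chunk <- body[(start + 2L):(hits[i + 1L] - 1L)]
    sep <- grepRaw("\r\n\r\n", chunk, fixed = TRUE)
    if (length(sep) == 0L) next
    headers <- rawToChar(chunk[1:(sep[1] - 1L)])
    content <- chunk[(sep[1] + 4L):(length(chunk) - 2L)]  # strip trailing CRLF
    m <- regmatches(headers, regexec('name="([^"]*)"', headers))[[1]]
    if (length(m) == 2L) parts[[m[2]]] <- content
  }
  parts
}

.encode_png_mask <- function(grid) {
  png::writePNG(grid / 255)  # stored 8-bit values are exactly 0/1
}

.decode_png_mask <- function(bytes) {
  img <- png::readPNG(bytes)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  (img > 0) * 1L
}

# --- client -----------------------------------------------------------------

#' Invoke a segmentation plugin endpoint
#'
#' Sends a multipart/form-data POST whose `file` field is the slice's
#' DICOM bytes passed through [anonymize] — identifying information never
#' leaves the process — plus one text field per metadata entry (at minimum
#' rows, cols, series_uid, instance_number and the region label). The
#' response must be `image/png` with the slice's shape; all non-zero pixels
#' are mapped to 1.
#'
#' @param endpoint plugin URL.
#' @param slice a [ct_slice] with `source_bytes`.
#' @param label region label forwarded to the plugin.
#' @param metadata named character list of extra text fields.
#' @param timeout request timeout in seconds.
#' @return a [roi_mask] of the slice's shape.
#' @export
call_plugin <- function(endpoint, slice, label = "region",
                        metadata = list(), timeout = 30) {
  if (is.null(slice$source_bytes)) {
    stop("slice has no source bytes; read it from a DICOM file first",
         call. = FALSE)
  }
  fields <- utils::modifyList(list(
    rows = as.character(slice$rows),
    cols = as.character(slice$cols),
    series_uid = slice$series_uid,
    instance_number = as.character(slice$instance_number),
    label = label
  ), as.list(metadata))
  h <- curl::new_handle(timeout = timeout)
  form <- c(list(file = curl::form_data(anonymize(slice$source_bytes),
                                        type = "application/dicom")),
            lapply(fields, curl::form_data))
  do.call(curl::handle_setform, c(list(h), form))
  res <- tryCatch(curl::curl_fetch_memory(endpoint, handle = h),
                  error = function(e) {
                    stop(sprintf("plugin request failed: %s",
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (res$status_code < 200 || res$status_code >= 300) {
    excerpt <- substr(rawToChar(res$content[res$content != as.raw(0)]), 1, 200)
    stop(sprintf("plugin error: HTTP %d: %s", res$status_code, excerpt),
         call. = FALSE)
  }
  ctype <- curl::parse_headers_list(res$headers)[["content-type"]]
  if (is.null(ctype) || !grepl("image/png", ctype, fixed = TRUE)) {
    stop(sprintf("protocol error: expected image/png, got '%s'", ctype),
         call. = FALSE)
  }
  mask <- .decode_png_mask(res$content)
  if (nrow(mask) != slice$rows || ncol(mask) != slice$cols) {
    stop(sprintf("protocol error: mask shape %dx%d does not match slice %dx%d",
                 nrow(mask), ncol(mask), slice$rows, slice$cols),
         call. = FALSE)
  }
  roi_mask(mask, label, slice)
}

#' Check that a captured plugin request transmits no identifying data
#'
#' Parses a captured multipart request body, extracts its `file` part and
#' verifies that the embedded DICOM carries none of the [dicom_phi_tags]
#' (nor any private element).
#'
#' @param request_bytes raw vector: the multipart request body as sent.
#' @return `TRUE` iff the embedded DICOM is fully de-identified.
#' @export
verify_anonymized_transmission <- function(request_bytes) {
  parts <- tryCatch(parse_multipart(request_bytes), error = function(e) NULL)
  if (is.null(parts) || is.null(parts$file)) return(FALSE)
  is_anonymized(parts$file)
}

# --- server -----------------------------------------------------------------

.http_text <- function(status, msg) {
  list(status = status,
       headers = list("Content-Type" = "text/plain; charset=utf-8"),
       body = msg)
}

.plugin_app <- function(registry, capture_dir = NULL) {
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  function(req) {
    name <- sub("^/", "", req$PATH_INFO)
    if (!name %in% names(registry)) {
      return(.http_text(404L, sprintf("unknown plugin '%s'", name)))
    }
    if (!identical(req$REQUEST_METHOD, "POST")) {
      return(.http_text(405L, "plugin endpoints accept POST only"))
    }
    body <- req$rook.input$read()
    if (!is.null(capture_dir)) {
      counter$n <- counter$n + 1L
      writeBin(body, file.path(capture_dir,
                               sprintf("request_%04d.bin", counter$n)))
    }
    boundary <- sub('.*boundary=\"?([^\";]+)\"?.*', "\\1",
                    req$CONTENT_TYPE %||% "")
    parts <- tryCatch(parse_multipart(body, boundary),
                      error = function(e) NULL)
    if (is.null(parts) || is.null(parts$file)) {
      return(.http_text(400L, "malformed multipart request: missing 'file' field"))
    }
    slice <- tryCatch({
      parsed <- dcm_parse(parts$file)
      .slice_from_parsed(parsed, parts$file)
    }, error = function(e) NULL)
    if (is.null(slice)) {
      return(.http_text(400L, "could not parse DICOM in 'file' field"))
    }
    mask <- tryCatch(registry[[name]](to_hu(slice)), error = function(e) e)
    if (inherits(mask, "error")) {
      return(.http_text(500L, sprintf("segmentation failed: %s",
                                      conditionMessage(mask))))
    }
    list(status = 200L,
         headers = list("Content-Type" = "image/png"),
         body = .encode_png_mask(mask))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serve segmentation plugins over HTTP
#'
#' Starts an HTTP service with one POST route per registered segmenter.
#' Each request is parsed as multipart/form-data, the `file` part is read
#' as DICOM and converted to HU, the named function is applied, and the
#' resulting binary mask is returned as `image/png`. Malformed requests get
#' 400, unknown routes 404, non-POST methods 405, internal failures 500.
#'
#' @param registry named list of functions `hu matrix -> 0/1 matrix`;
#'   default: the built-in segmenters (`sfa`, `vfa`, `taa`, `muscle`).
#' @param port TCP port; 0 picks a free port.
#' @param host bind address.
#' @param blocking if `TRUE`, runs the event loop forever (for a standalone
#'   server process); if `FALSE`, returns the `httpuv` server handle (the
#'   caller drives the loop or uses it from another process).
#' @param capture_dir optional directory where each raw request body is
#'   dumped (`request_NNNN.bin`), for transmission audits.
#' @return invisibly, a list with `port` and (non-blocking) the server
#'   handle.
#' @export
serve_plugins <- function(registry = autoseg_registry(), port = 0L,
                          host = "127.0.0.1", blocking = TRUE,
                          capture_dir = NULL) {
  stopifnot(length(registry) >= 1, !is.null(names(registry)))
  if (port == 0L) port <- httpuv::randomPort(host = host)
  app <- list(call = .plugin_app(registry, capture_dir))
  server <- httpuv::startServer(host, port, app)
  message(sprintf("serving plugins [%s] on %s:%d",
                  paste(names(registry), collapse = ", "), host, port))
  if (blocking) {
    on.exit(httpuv::stopServer(server))
    httpuv::service(Inf)
  }
  invisible(list(port = port, server = if (!blocking) server))
}
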