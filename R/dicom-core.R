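# Low-level DICOM Part 10 parsing and serialization.
#
# Scope: uncompressed little-endian transfer syntaxes only (explicit VR
# 1.2.840.10008.1.2.1 and implicit VR 1.2.840.10008.1.2). Compressed or
# big-endian syntaxes raise a named error; this package never decodes
# JPEG/JPEG2000 pixel streams itself.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.vr_long <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Minimal tag dictionary: enough to assign a VR when reading implicit-VR
# files and to build our own writer. Keys are "GGGG,EEEE" (uppercase hex).
.dcm_dict <- c(
  "0002,0001" = "OB", "0002,0002" = "UI", "0002,0003" = "UI",
  "0002,0010" = "UI", "0002,0012" = "UI",
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0020" = "DA",
  "0008,0050" = "SH", "0008,0060" = "CS", "0008,0070" = "LO",
  "0008,0080" = "LO", "0008,0081" = "ST", "0008,0090" = "PN",
  "0008,1050" = "PN", "0008,1070" = "PN",
  "0010,0010" = "PN", "0010,0020" = "LO", "0010,0030" = "DA",
  "0010,1000" = "LO", "0010,1040" = "LO",
  "0018,0050" = "DS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0010" = "SH",
  "0020,0013" = "IS", "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "7FE0,0010" = "OW"
)

tag_key <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

.u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}

.u32 <- function(bytes, pos) {
  v <- readBin(bytes[pos:(pos + 3L)], "numeric", size = 4L, endian = "little")
  # readBin can't read unsigned 32-bit; go via two uint16 halves
  lo <- .u16(bytes, pos)
  hi <- .u16(bytes, pos + 2L)
  lo + hi * 65536
}

.enc_u16 <- function(x) {
  writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}

.enc_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  c(.enc_u16(lo), .enc_u16(hi))
}

#' @noRd
dcm_element <- function(group, element, vr, bytes) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, bytes = bytes)
}

# Encode an R value into element bytes according to VR. Strings are padded
# to even length (NUL for UI, space otherwise); multi-valued numeric string
# VRs are joined with backslash.
dcm_make <- function(group, element, vr, value) {
  bytes <- if (vr %in% c("US",  "SS")) {
    .enc_u16(value)
  } else if (vr == "UL") {
    .enc_u32(value)
  } else if (vr %in% c("OB", "OW", "UN")) {
    as.raw(value)
  } else {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      b <- c(b, pad)
    }
    b
  }
  dcm_element(group, element, vr, bytes)
}

# --- parsing ----------------------------------------------------------------

# Parse one element starting at pos; returns list(el, next_pos).
# `explicit` selects the VR encoding.
.parse_element <- function(bytes, pos, explicit) {
  n <- length(bytes)
  if (pos + 7L > n + 1L) stop("truncated DICOM element", call. = FALSE)
  group <- .u16(bytes, pos)
  element <- .u16(bytes, pos + 2L)
  pos <- pos + 4L

  if (group == 0xFFFEL) {
    # item / delimiter tags carry no VR
    len <- .u32(bytes, pos)
    return(list(group = group, element = element, vr = "",
                len = len, data_pos = pos + 4L))
  }

  if (explicit) {
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% .vr_long) {
      len <- .u32(bytes, pos + 2L)
      pos <- pos + 6L
    } else {
      len <- .u16(bytes, pos)
      pos <- pos + 2L
    }
  } else {
    key <- tag_key(group, element)
    vr <- if (!is.na(.dcm_dict[key])) unname(.dcm_dict[key]) else "UN"
    len <- .u32(bytes, pos)
    pos <- pos + 4L
  }
  list(group = group, element = element, vr = vr, len = len, data_pos = pos)
}

# Skip an undefined-length sequence starting at data_pos; returns position
# just past the sequence delimiter. Handles nested undefined-length items.
.skip_undefined_sq <- function(bytes, pos, explicit) {
  repeat {
    group <- .u16(bytes, pos); element <- .u16(bytes, pos + 2L)
    len <- .u32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFEL && element == 0xE0DDL) return(pos)  # sequence end
    if (group == 0xFFFEL && element == 0xE000L) {            # item
      if (len == 4294967295) {
        # undefined-length item: scan elements until item delimiter
        repeat {
          g2 <- .u16(bytes, pos); e2 <- .u16(bytes, pos + 2L)
          if (g2 == 0xFFFEL && e2 == 0xE00DL) { pos <- pos + 8L; break }
          h <- .parse_element(bytes, pos, explicit)
          pos <- if (h$vr == "SQ" && h$len == 4294967295) {
            .skip_undefined_sq(bytes, h$data_pos, explicit)
          } else h$data_pos + h$len
        }
      } else {
        pos <- pos + len
      }
    } else {
      stop("malformed sequence encoding", call. = FALSE)
    }
  }
}

# Parse a dataset (element list) from pos to end (or while group == `group`).
.parse_dataset <- function(bytes, pos, explicit, stop_after_group = NULL) {
  elements <- list()
  n <- length(bytes)
  while (pos <= n - 7L) {
    peek_group <- .u16(bytes, pos)
    if (!is.null(stop_after_group) && peek_group != stop_after_group) break
    h <- .parse_element(bytes, pos, explicit)
    if (h$vr == "SQ" && h$len == 4294967295) {
      end <- .skip_undefined_sq(bytes, h$data_pos, explicit)
      val <- bytes[h$data_pos:(end - 1L)]
      elements[[length(elements) + 1L]] <-
        dcm_element(h$group, h$element, "SQ", val)
      attr(elements[[length(elements)]], "undefined_length") <- TRUE
      pos <- end
      next
    }
    if (h$len == 4294967295) {
      stop("unsupported undefined-length element (encapsulated pixel data?)",
           call. = FALSE)
    }
    val <- if (h$len > 0L) bytes[h$data_pos:(h$data_pos + h$len - 1L)] else raw(0)
    elements[[length(elements) + 1L]] <- dcm_element(h$group, h$element, h$vr, val)
    pos <- h$data_pos + h$len
  }
  list(elements = elements, pos = pos)
}

#' Parse a DICOM Part 10 file from raw bytes
#'
#' Returns the file meta group and dataset as flat element lists. Only
#' uncompressed little-endian transfer syntaxes are supported; compressed
#' syntaxes raise an error of class \code{ctmorph_unsupported_syntax}.
#' @noRd
dcm_parse <- function(bytes) {
  if (!is.raw(bytes)) stop("expected raw vector", call. = FALSE)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file (missing DICM magic)", call. = FALSE)
  }
  meta <- .parse_dataset(bytes, 133L, explicit = TRUE, stop_after_group = 2L)
  ts_el <- dcm_find(meta$elements, 0x0002L, 0x0010L)
  ts <- if (is.null(ts_el)) TS_IMPLICIT_LE else dcm_str(ts_el)
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE)) {
    stop(structure(
      class = c("ctmorph_unsupported_syntax", "error", "condition"),
      list(message = sprintf(
             "unsupported transfer syntax '%s' (compressed or big-endian DICOM is not handled)",
             ts),
           call = NULL)))
  }
  data <- .parse_dataset(bytes, meta$pos, explicit = ts == TS_EXPLICIT_LE)
  list(meta = meta$elements, data = data$elements, transfer_syntax = ts)
}

# --- element access ---------------------------------------------------------

dcm_find <- function(elements, group, element) {
  for (el in elements) {
    if (el$group == group && el$element == element) return(el)
  }
  NULL
}

dcm_str <- function(el) {
  if (is.null(el) || length(el$bytes) == 0L) return("")
  s <- rawToChar(el$bytes[el$bytes != as.raw(0L)])
  sub("[ ]+$", "", s)
}

dcm_ds <- function(el) {
  if (is.null(el)) return(numeric(0))
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NA_integer_)
  .u16(el$bytes, 1L)
}

# --- serialization ----------------------------------------------------------

.serialize_element <- function(el, explicit) {
  tag <- c(.enc_u16(el$group), .enc_u16(el$element))
  len <- length(el$bytes)
  if (explicit) {
    if (el$vr %in% .vr_long || el$vr == "SQ") {
      c(tag, charToRaw(el$vr), as.raw(c(0L, 0L)), .enc_u32(len), el$bytes)
    } else {
      c(tag, charToRaw(el$vr), .enc_u16(len), el$bytes)
    }
  } else {
    c(tag, .enc_u32(len), el$bytes)
  }
}

#' Serialize meta + data element lists back to Part 10 bytes.
#' File meta is always explicit VR LE; the dataset follows `transfer_syntax`.
#' @noRd
dcm_serialize <- function(meta, data, transfer_syntax = TS_EXPLICIT_LE) {
  explicit <- transfer_syntax == TS_EXPLICIT_LE
  # drop any pre-existing group length; recompute
  meta <- Filter(function(el) !(el$group == 2L && el$element == 0L), meta)
  ts_el <- dcm_find(meta, 0x0002L, 0x0010L)
  if (is.null(ts_el)) {
    meta <- c(meta, list(dcm_make(0x0002L, 0x0010L, "UI", transfer_syntax)))
  }
  meta <- meta[order(vapply(meta, function(e) e$element, integer(1)))]
  meta_bytes <- do.call(c, lapply(meta, .serialize_element, explicit = TRUE))
  gl <- .serialize_element(dcm_make(0x0002L, 0x0000L, "UL",
                                    length(meta_bytes)), explicit = TRUE)
  ord <- order(vapply(data, function(e) e$group, integer(1)),
               vapply(data, function(e) e$element, integer(1)))
  data_bytes <- do.call(c, lapply(data[ord], .serialize_element,
                                  explicit = explicit))
  c(raw(128L), charToRaw("DICM"), gl, meta_bytes, data_bytes)
}

# Deterministic UID under a numeric suffix; root is an unregistered
# example-style org root used only for synthetic data.
.uid_root <- "1.2.826.0.1.3680043.10.1437"
make_uid <- function(...) {
  paste(c(.uid_root, as.character(c(...))), collapse = ".")
}
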