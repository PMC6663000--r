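#' Read an FCS 3.0 / 3.1 list-mode file
#'
#' Parses the FCS header, TEXT segment and DATA segment of a list-mode
#' file and returns the events as an [event_table]. Channel names are
#' taken from the `$PnN` keywords (falling back to `$PnS`). Sample
#' metadata is populated from TEXT keywords where present
#' (`SPOREGATE_SAMPLE_ID`, `SPOREGATE_STRAIN`, `SPOREGATE_TIME_H`,
#' `SPOREGATE_REPLICATE`, `$FIL`); the full keyword list is kept in
#' `metadata$keywords`.
#'
#' Supported data layouts: `$MODE L` (list mode) with `$DATATYPE` `F`
#' (32-bit float), `D` (64-bit double) or `I` (unsigned integers of a
#' common `$PnB` of 8, 16, 32 or 64 bits), byte order `1,2,3,4` or
#' `4,3,2,1`. Anything else raises an error. Compensation and gain/log
#' amplification (`$PnE` other than `0,0`) are out of scope and raise
#' an error rather than silently mis-reading.
#'
#' @param path path to an FCS file.
#' @return an [event_table].
#' @seealso [write_fcs()], [subsample_events()]
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stopf("FCS file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  header <- readBin(con, "raw", 58L)
  if (length(header) < 58L) stopf("truncated FCS file (header): %s", path)
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stopf("unsupported FCS version '%s' (only FCS 3.0/3.1 are read)", version)
  }
  off <- function(i) {
    s <- trimws(rawToChar(header[(11 + 8 * (i - 1)):(10 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.double(s))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (is.na(text_beg) || is.na(text_end) || text_end < text_beg) {
    stopf("malformed FCS header offsets in %s", path)
  }

  seek(con, text_beg)
  text_raw <- readBin(con, "raw", text_end - text_beg + 1)
  if (length(text_raw) < text_end - text_beg + 1) {
    stopf("truncated FCS file (TEXT segment): %s", path)
  }
  kw <- parse_fcs_text(text_raw)
  getkw <- function(key, default = NULL) {
    v <- kw[[toupper(key)]]
    if (is.null(v) || !nzchar(v)) default else v
  }

  mode <- getkw("$MODE", "L")
  if (!identical(mode, "L")) {
    stopf("unsupported $MODE '%s': only list mode (L) is supported", mode)
  }
  n_par <- as.integer(getkw("$PAR", NA))
  n_tot <- as.integer(getkw("$TOT", NA))
  if (is.na(n_par) || is.na(n_tot)) stopf("missing $PAR or $TOT in %s", path)

  dtype <- getkw("$DATATYPE", "F")
  byteord <- getkw("$BYTEORD", "1,2,3,4")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stopf("unsupported $BYTEORD '%s'", byteord))

  ch_names <- character(n_par)
  bits <- integer(n_par)
  for (i in seq_len(n_par)) {
    ch_names[i] <- getkw(sprintf("$P%dN", i),
                         getkw(sprintf("$P%dS", i), sprintf("P%d", i)))
    bits[i] <- as.integer(getkw(sprintf("$P%dB", i), "32"))
    amp <- getkw(sprintf("$P%dE", i), "0,0")
    if (!identical(gsub(" ", "", amp), "0,0")) {
      stopf("log-amplified parameter $P%dE='%s' is not supported", i, amp)
    }
  }

  # FCS 3.x stores data offsets in TEXT when they overflow the header.
  if (data_beg == 0) data_beg <- as.double(getkw("$BEGINDATA", "0"))
  if (data_end == 0) data_end <- as.double(getkw("$ENDDATA", "0"))

  if (n_tot == 0L) {
    return(event_table(matrix(numeric(0), 0, n_par), ch_names,
                       fcs_metadata(kw, path)))
  }
  if (data_beg <= 0 || data_end < data_beg) {
    stopf("malformed DATA offsets in %s", path)
  }

  n_values <- n_par * n_tot
  seek(con, data_beg)
  if (dtype == "F") {
    if (any(bits != 32L)) stopf("$DATATYPE F requires $PnB=32")
    vals <- readBin(con, "numeric", n_values, size = 4, endian = endian)
  } else if (dtype == "D") {
    if (any(bits != 64L)) stopf("$DATATYPE D requires $PnB=64")
    vals <- readBin(con, "numeric", n_values, size = 8, endian = endian)
  } else if (dtype == "I") {
    nb <- unique(bits)
    if (length(nb) != 1L || !nb %in% c(8L, 16L, 32L, 64L)) {
      stopf("$DATATYPE I requires a common $PnB of 8, 16, 32 or 64")
    }
    if (nb == 64L) {
      vals <- readBin(con, "numeric", n_values, size = 8, endian = endian)
    } else {
      vals <- readBin(con, "integer", n_values, size = nb %/% 8,
                      signed = nb < 32L, endian = endian)
      if (nb == 32L) vals[vals < 0] <- vals[vals < 0] + 2^32
      vals <- as.double(vals)
    }
  } else {
    stopf("unsupported $DATATYPE '%s'", dtype)
  }
  if (length(vals) < n_values) {
    stopf("truncated FCS file (DATA segment): %s", path)
  }
  events <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  event_table(events, ch_names, fcs_metadata(kw, path))
}

#' Write an event table as an FCS 3.1 file
#'
#' Emits FCS 3.1 list-mode with `$DATATYPE F` (32-bit float),
#' little-endian byte order, and one `$PnN` keyword per channel. Sample
#' metadata (`sample_id`, `strain`, `time_h`, `replicate`) is stored as
#' custom `SPOREGATE_*` TEXT keywords so that [read_fcs()] round-trips it.
#'
#' @param table an [event_table] with at least one channel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  p <- length(channels(table))
  if (p < 1L) stopf("cannot write an FCS file with zero channels")
  n <- n_events(table)
  ev <- table$events

  kw <- list("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
             "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
             "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
             "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
             "$NEXTDATA" = "0", "$PAR" = as.character(p),
             "$TOT" = as.character(n))
  for (i in seq_len(p)) {
    rng <- if (n > 0) max(1, ceiling(max(ev[, i]))) else 262144
    kw[[sprintf("$P%dN", i)]] <- channels(table)[i]
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- as.character(rng)
  }
  md <- table$metadata
  put_md <- function(key, value) {
    if (!is.null(value) && !is.na(value)[1] && nzchar(as.character(value)[1])) {
      kw[[key]] <<- as.character(value)[1]
    }
  }
  put_md("SPOREGATE_SAMPLE_ID", md$sample_id)
  put_md("SPOREGATE_STRAIN", md$strain)
  put_md("SPOREGATE_TIME_H", md$time_h)
  put_md("SPOREGATE_REPLICATE", md$replicate)

  delim <- "/"
  esc <- function(x) gsub(delim, paste0(delim, delim), x, fixed = TRUE)
  build_text <- function(kws) {
    paste0(delim,
           paste0(vapply(names(kws), esc, ""), delim,
                  vapply(unlist(kws), esc, ""), delim, collapse = ""))
  }
  # $BEGINDATA/$ENDDATA are written fixed-width so the TEXT length does
  # not change once the real offsets are substituted in.
  draft <- build_text(kw)
  text_beg <- 58L
  text_len <- nchar(draft, type = "bytes") - nchar("%BD%%ED%") + 16L
  data_beg <- text_beg + text_len
  n_bytes <- 4 * n * p
  data_end <- if (n > 0) data_beg + n_bytes - 1 else 0
  kw[["$BEGINDATA"]] <- sprintf("%8d", if (n > 0) data_beg else 0)
  kw[["$ENDDATA"]] <- sprintf("%8d", data_end)
  text <- build_text(kw)
  stopifnot(nchar(text, type = "bytes") == text_len)

  hdr_num <- function(x) {
    if (x > 99999999) stopf("segment offset exceeds FCS header capacity")
    sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ",
                   hdr_num(text_beg), hdr_num(text_beg + text_len - 1),
                   hdr_num(if (n > 0) data_beg else 0), hdr_num(data_end),
                   hdr_num(0), hdr_num(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (n > 0) {
    writeBin(as.vector(t(ev)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Subsample events without replacement
#'
#' Cytometric acquisitions are routinely evaluated on a fixed number of
#' events (1e5 per analysis here); this draws a uniform random subsample
#' without replacement when the table is larger than `n_max` and returns
#' the table unchanged otherwise. The original acquisition order of the
#' retained events is preserved.
#'
#' @param table an [event_table].
#' @param n_max maximum number of events to keep (default 100000).
#' @param seed integer RNG seed; the same seed always yields the same
#'   subsample.
#' @return an [event_table] with at most `n_max` events.
#' @export
subsample_events <- function(table, n_max = 100000L, seed = 20190729L) {
  stopifnot(inherits(table, "event_table"))
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1) {
    stopf("`n_max` must be a single count >= 1")
  }
  n <- n_events(table)
  if (n <= n_max) return(table)
  idx <- with_seed(seed, sample.int(n, size = as.integer(n_max)))
  subset_events(table, sort(idx))
}

#' Read a sample sheet
#'
#' Experimental design (strain, time point, replicate) lives outside the
#' FCS files; a sidecar CSV supplies it. Required columns: `sample_id`,
#' `path`; optional: `strain`, `time_h`, `replicate`. Relative paths are
#' resolved against the sheet's own directory.
#'
#' @param path path to the CSV sample sheet.
#' @return a data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols)) {
    stopf("sample sheet is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stopf("sample sheet has duplicated sample_id values")
  }
  for (col in c("strain", "time_h", "replicate")) {
    if (is.null(sheet[[col]])) sheet[[col]] <- NA
  }
  sheet$time_h <- suppressWarnings(as.numeric(sheet$time_h))
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet
}

# -- internal ---------------------------------------------------------------

# Parse a raw TEXT segment into a named list of keyword values, honouring
# the FCS escaping rule (a doubled delimiter inside a value is a literal).
parse_fcs_text <- function(raw) {
  if (length(raw) < 2) stopf("empty FCS TEXT segment")
  delim <- rawToChar(raw[1])
  chars <- strsplit(rawToChar(raw[-1]), "", fixed = TRUE)[[1]]
  tokens <- character(0)
  buf <- character(0)
  i <- 1L
  nch <- length(chars)
  while (i <= nch) {
    ch <- chars[i]
    if (ch != delim) {
      buf <- c(buf, ch)
      i <- i + 1L
    } else if (i < nch && chars[i + 1L] == delim) {
      buf <- c(buf, delim)
      i <- i + 2L
    } else {
      tokens <- c(tokens, paste(buf, collapse = ""))
      buf <- character(0)
      i <- i + 1L
    }
  }
  if (length(buf)) tokens <- c(tokens, paste(buf, collapse = ""))
  if (length(tokens) %% 2L == 1L) tokens <- tokens[-length(tokens)]
  keys <- tokens[seq(1, length(tokens), by = 2)]
  vals <- tokens[seq(2, length(tokens), by = 2)]
  keys <- ifelse(startsWith(keys, "$"), toupper(keys), keys)
  stats::setNames(as.list(vals), keys)
}

fcs_metadata <- function(kw, path) {
  sid <- kw[["SPOREGATE_SAMPLE_ID"]] %||% kw[["$FIL"]] %||%
    sub("\\.fcs$", "", basename(path), ignore.case = TRUE)
  th <- kw[["SPOREGATE_TIME_H"]]
  list(sample_id = sid,
       strain = kw[["SPOREGATE_STRAIN"]],
       time_h = if (!is.null(th)) as.numeric(th) else NULL,
       replicate = kw[["SPOREGATE_REPLICATE"]],
       keywords = kw)
}
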