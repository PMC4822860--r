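# Praat TextGrid input/output. Both text dialects that Praat emits are
# accepted: the "long" format (keyword = value lines) and the "short" format
# (bare values). Files may be UTF-8 (with or without BOM) or UTF-16.

#' Read phrase annotations from a Praat TextGrid
#'
#' Reads one interval tier of a TextGrid file and returns its non-empty
#' intervals as phrase events; empty-text intervals (silence) are skipped.
#' Labels are whitespace-trimmed but case-sensitive.
#'
#' @param path path to a TextGrid file (long or short text format; UTF-8 or
#'   UTF-16).
#' @param tier_name name of the interval tier holding phrase labels.
#' @param individual_id,recorded_at optional recording metadata to attach.
#' @return a [song_recording()].
#' @export
read_textgrid <- function(path, tier_name = "phrases",
                          individual_id = "unknown", recorded_at = NA) {
  lines <- read_textgrid_lines(path)
  tiers <- if (is_long_textgrid(lines)) {
    parse_textgrid_long(lines, path)
  } else {
    parse_textgrid_short(lines, path)
  }
  names_avail <- vapply(tiers, `[[`, character(1L), "name")
  hit <- which(names_avail == tier_name)
  if (length(hit) == 0L) {
    stop("tier '", tier_name, "' not found in ", path,
         " (available: ", paste(names_avail, collapse = ", "), ")", call. = FALSE)
  }
  tier <- tiers[[hit[1L]]]
  lab <- trimws(tier$text)
  keep <- nzchar(lab)
  song_recording(labels = lab[keep], start = tier$xmin[keep],
                 end = tier$xmax[keep], individual_id = individual_id,
                 recorded_at = recorded_at, source = basename(path))
}

read_textgrid_lines <- function(path) {
  bom <- readBin(path, "raw", n = 2L)
  enc <- if (length(bom) == 2L &&
             ((bom[1L] == as.raw(0xfe) && bom[2L] == as.raw(0xff)) ||
              (bom[1L] == as.raw(0xff) && bom[2L] == as.raw(0xfe)))) {
    "UTF-16"
  } else {
    "UTF-8"
  }
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # strip a UTF-8 BOM if present
  if (length(lines) > 0L) lines[1L] <- sub("^﻿", "", lines[1L])
  lines
}

is_long_textgrid <- function(lines) {
  any(grepl("^\\s*item\\s*\\[", lines[seq_len(min(30L, length(lines)))]))
}

tg_error <- function(path, i, msg) {
  stop("malformed TextGrid ", path, " at line ", i, ": ", msg, call. = FALSE)
}

# Praat doubles embedded quotes inside quoted strings.
tg_unquote <- function(s) gsub("\"\"", "\"", s, fixed = TRUE)

parse_textgrid_long <- function(lines, path) {
  tiers <- list()
  cur <- NULL
  in_points <- FALSE
  num_of <- function(line, i) {
    v <- suppressWarnings(as.numeric(sub("^.*=\\s*", "", line)))
    if (is.na(v)) tg_error(path, i, "expected a number")
    v
  }
  str_of <- function(line, i) {
    m <- regmatches(line, regexec("=\\s*\"(.*)\"\\s*$", line))[[1L]]
    if (length(m) < 2L) tg_error(path, i, "expected a quoted string")
    tg_unquote(m[2L])
  }
  pending <- NULL # interval under construction: list(xmin, xmax)
  flush_interval <- function(text) {
    cur$xmin <<- c(cur$xmin, pending$xmin)
    cur$xmax <<- c(cur$xmax, pending$xmax)
    cur$text <<- c(cur$text, text)
    pending <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^item\\s*\\[\\s*[0-9]+\\s*\\]", ln)) {
      if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
      cur <- list(class = NA_character_, name = NA_character_,
                  xmin = numeric(0), xmax = numeric(0), text = character(0))
      in_points <- FALSE
      pending <- NULL
    } else if (is.null(cur)) {
      next
    } else if (grepl("^class\\s*=", ln)) {
      cur$class <- str_of(ln, i)
      in_points <- !identical(cur$class, "IntervalTier")
    } else if (grepl("^name\\s*=", ln)) {
      cur$name <- str_of(ln, i)
    } else if (in_points) {
      next
    } else if (grepl("^intervals\\s*\\[", ln)) {
      pending <- list(xmin = NA_real_, xmax = NA_real_)
    } else if (!is.null(pending) && grepl("^xmin\\s*=", ln)) {
      pending$xmin <- num_of(ln, i)
    } else if (!is.null(pending) && grepl("^xmax\\s*=", ln)) {
      pending$xmax <- num_of(ln, i)
    } else if (!is.null(pending) && grepl("^text\\s*=", ln)) {
      flush_interval(str_of(ln, i))
    }
  }
  if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
  if (length(tiers) == 0L) tg_error(path, length(lines), "no tiers found")
  Filter(function(t) identical(t$class, "IntervalTier"), tiers)
}

parse_textgrid_short <- function(lines, path) {
  # token stream: drop the two header lines and blanks
  toks <- trimws(lines)
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2L || !grepl("ooTextFile", toks[1L]) ||
      !grepl("TextGrid", toks[2L])) {
    tg_error(path, 1L, "missing TextGrid header")
  }
  toks <- toks[-c(1L, 2L)]
  p <- 0L
  take <- function() {
    p <<- p + 1L
    if (p > length(toks)) tg_error(path, p, "unexpected end of file")
    toks[p]
  }
  take_num <- function() {
    v <- suppressWarnings(as.numeric(take()))
    if (is.na(v)) tg_error(path, p, "expected a number")
    v
  }
  take_str <- function() {
    s <- take()
    if (!grepl("^\".*\"$", s)) tg_error(path, p, "expected a quoted string")
    tg_unquote(substr(s, 2L, nchar(s) - 1L))
  }
  take_num(); take_num()          # global xmin, xmax
  take()                          # tiers? flag
  ntier <- take_num()
  tiers <- vector("list", ntier)
  for (t in seq_len(ntier)) {
    cls <- take_str()
    nm <- take_str()
    take_num(); take_num()        # tier xmin, xmax
    n <- take_num()
    if (identical(cls, "IntervalTier")) {
      xmin <- numeric(n); xmax <- numeric(n); text <- character(n)
      for (j in seq_len(n)) {
        xmin[j] <- take_num(); xmax[j] <- take_num(); text[j] <- take_str()
      }
      tiers[[t]] <- list(class = cls, name = nm, xmin = xmin, xmax = xmax,
                         text = text)
    } else {
      for (j in seq_len(n)) { take_num(); take_str() } # point tier: skip
      tiers[[t]] <- list(class = cls, name = nm)
    }
  }
  Filter(function(t) identical(t$class, "IntervalTier"), tiers)
}

#' Write a recording as a Praat TextGrid
#'
#' Writes the long text format (UTF-8) with one interval tier; gaps between
#' phrases become empty (silence) intervals so the tier tiles the full time
#' axis, as Praat requires.
#'
#' @param recording a [song_recording()].
#' @param path output file path.
#' @param tier_name name for the interval tier.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(recording, path, tier_name = "phrases") {
  st <- recording$start
  en <- recording$end
  lab <- recording$labels
  xmin <- if (length(st)) min(0, st[1L]) else 0
  xmax <- if (length(en)) max(en) else 1
  # tile with silence intervals
  ix <- numeric(0); ax <- numeric(0); tx <- character(0)
  cursor <- xmin
  for (j in seq_along(lab)) {
    if (st[j] > cursor + 1e-12) {
      ix <- c(ix, cursor); ax <- c(ax, st[j]); tx <- c(tx, "")
    }
    ix <- c(ix, st[j]); ax <- c(ax, en[j]); tx <- c(tx, lab[j])
    cursor <- en[j]
  }
  if (cursor < xmax - 1e-12 || length(lab) == 0L) {
    ix <- c(ix, cursor); ax <- c(ax, xmax); tx <- c(tx, "")
  }
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  q <- function(s) paste0("\"", gsub("\"", "\"\"", s, fixed = TRUE), "\"")
  out <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    paste0("xmin = ", fmt(xmin)),
    paste0("xmax = ", fmt(xmax)),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    "        class = \"IntervalTier\"",
    paste0("        name = ", q(tier_name)),
    paste0("        xmin = ", fmt(xmin)),
    paste0("        xmax = ", fmt(xmax)),
    paste0("        intervals: size = ", length(ix))
  )
  body <- character(0)
  for (j in seq_along(ix)) {
    body <- c(body,
              paste0("        intervals [", j, "]:"),
              paste0("            xmin = ", fmt(ix[j])),
              paste0("            xmax = ", fmt(ax[j])),
              paste0("            text = ", q(tx[j])))
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(out, body), con)
  invisible(path)
}

#' Read a directory of TextGrids into per-individual corpora
#'
#' The metadata table (CSV with columns `recording_id`, `individual_id`,
#' `datetime` in ISO-8601, and `path` relative to `dir`) drives corpus
#' assembly; recordings are ordered chronologically within each individual.
#'
#' @param dir directory containing TextGrid files and the metadata table.
#' @param metadata metadata CSV file name within `dir`.
#' @param tier_name interval tier holding phrase labels.
#' @return a named list of [song_corpus()] objects, one per individual.
#' @export
read_corpus <- function(dir, metadata = "metadata.csv", tier_name = "phrases") {
  meta <- utils::read.csv(file.path(dir, metadata), stringsAsFactors = FALSE)
  need <- c("recording_id", "individual_id", "datetime", "path")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (ind in unique(meta$individual_id)) {
    rows <- meta[meta$individual_id == ind, , drop = FALSE]
    recs <- lapply(seq_len(nrow(rows)), function(i) {
      r <- read_textgrid(file.path(dir, rows$path[i]), tier_name,
                         individual_id = ind,
                         recorded_at = rows$datetime[i])
      r$source <- rows$recording_id[i]
      r
    })
    out[[ind]] <- song_corpus(recs, ind)
  }
  out
}

#' Write corpora as TextGrids plus a metadata table
#'
#' Inverse of [read_corpus()]: one TextGrid per recording and a
#' `metadata.csv` indexing them.
#'
#' @param corpora a `song_corpus` or a list of them.
#' @param dir output directory (created if needed).
#' @param tier_name interval tier name to write.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpora, dir, tier_name = "phrases") {
  if (inherits(corpora, "song_corpus")) corpora <- list(corpora)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (corpus in corpora) {
    ids <- recording_ids(corpus)
    for (i in seq_along(corpus$recordings)) {
      rec <- corpus$recordings[[i]]
      fname <- paste0(corpus$individual_id, "_", ids[i], ".TextGrid")
      write_textgrid(rec, file.path(dir, fname), tier_name)
      ts <- rec$recorded_at
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = ids[i], individual_id = corpus$individual_id,
        datetime = if (inherits(ts, "POSIXct")) {
          format(ts, "%Y-%m-%dT%H:%M:%S")
        } else NA_character_,
        path = fname, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
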