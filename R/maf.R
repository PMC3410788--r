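## UCSC MAF (Multiple Alignment Format) reading and writing. Rows carry
## strand-relative 0-based starts, ungapped sizes and source lengths; "i",
## "e" and "q" lines are tolerated and ignored. No installed package parses
## MAF, so the (line-oriented, trivial) format is handled here directly.

maf_block <- function(score, src, start, size, strand, srcSize, text) {
  rows <- data.frame(src = unname(src), start = as.integer(unname(start)),
                     size = as.integer(unname(size)), strand = unname(strand),
                     srcSize = as.integer(unname(srcSize)), text = unname(text),
                     stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  structure(list(score = score, rows = rows), class = "maf_block")
}

validate_maf_block <- function(block, idx = NA) {
  r <- block$rows
  where <- if (is.na(idx)) "" else sprintf(" (block %d)", idx)
  if (length(unique(nchar(r$text))) > 1L)
    stopf("MAF row texts differ in length%s", where)
  nongap <- nchar(gsub("-", "", r$text, fixed = TRUE))
  bad <- which(nongap != r$size)
  if (length(bad))
    stopf("MAF row '%s': non-gap count %d != size %d%s",
          r$src[bad[1L]], nongap[bad[1L]], r$size[bad[1L]], where)
  over <- which(r$start + r$size > r$srcSize)
  if (length(over))
    stopf("MAF row '%s': start + size exceeds srcSize%s", r$src[over[1L]], where)
  invisible(block)
}

#' Parse a UCSC MAF file into alignment blocks
#'
#' @param path MAF file path.
#' @return A list of `maf_block` objects, each with a `score` and a `rows`
#'   data.frame (`src`, `start`, `size`, `strand`, `srcSize`, `text`).
#' @export
parse_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur$rows) > 0L) {
      blk <- maf_block(cur$score, cur$rows$src, cur$rows$start, cur$rows$size,
                       cur$rows$strand, cur$rows$srcSize, cur$rows$text)
      validate_maf_block(blk, length(blocks) + 1L)
      blocks[[length(blocks) + 1L]] <<- blk
    }
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (f[1L] == "a") {
      flush()
      score <- NA_real_
      sc <- grep("^score=", f, value = TRUE)
      if (length(sc)) score <- as.numeric(sub("score=", "", sc[1L]))
      cur <- list(score = score,
                  rows = data.frame(src = character(), start = integer(),
                                    size = integer(), strand = character(),
                                    srcSize = integer(), text = character(),
                                    stringsAsFactors = FALSE))
    } else if (f[1L] == "s") {
      if (is.null(cur)) stopf("%s: 's' line outside an 'a' block", path)
      if (length(f) != 7L) stopf("%s: malformed 's' line: %s", path, ln)
      cur$rows <- rbind(cur$rows, data.frame(
        src = f[2L], start = as.integer(f[3L]), size = as.integer(f[4L]),
        strand = f[5L], srcSize = as.integer(f[6L]), text = toupper(f[7L]),
        stringsAsFactors = FALSE))
    }
    # i / e / q lines ignored
  }
  flush()
  blocks
}

#' Write alignment blocks as MAF
#'
#' @param blocks List of `maf_block` objects.
#' @param path Output path.
#' @export
write_maf <- function(blocks, path) {
  out <- "##maf version=1"
  for (b in blocks) {
    score <- if (is.na(b$score)) "" else sprintf(" score=%g", b$score)
    out <- c(out, paste0("a", score))
    r <- b$rows
    out <- c(out, sprintf("s %s %d %d %s %d %s",
                          r$src, r$start, r$size, r$strand, r$srcSize, r$text))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

## Species name = the MAF src prefix before the first dot.
maf_species <- function(src) sub("\\..*$", "", src)

## Forward-strand half-open interval of a MAF row.
maf_row_forward <- function(start, size, strand, srcSize) {
  if (strand == "+") c(start, start + size) else c(srcSize - start - size, srcSize - start)
}
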