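#' Read a motif library in MEME minimal format
#'
#' Parses `MOTIF` blocks with their letter-probability matrices into a list
#' of position weight matrices (4 x width, rows A/C/G/T, columns summing
#' to 1). Columns off unity by at most `1e-3` are renormalised; worse
#' deviations are an error naming the motif.
#'
#' @param path Path to a MEME minimal text file.
#' @return A `motif_library`: list of motifs, each with `motif_id`, `width`
#'   and `mat` (4 x width probability matrix).
#' @export
read_motif_database <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) abort("no MOTIF blocks found in MEME file")
  motifs <- vector("list", length(motif_at))
  for (i in seq_along(motif_at)) {
    hdr <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1L]]
    motif_id <- hdr[[2L]]
    # find the letter-probability header, then read `w` numeric rows
    j <- motif_at[i] + 1L
    while (j <= length(lines) &&
           !grepl("letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) {
      abort(paste0("motif ", motif_id, ": no letter-probability matrix"))
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(lengths(vals) != 4L)) {
      abort(paste0("motif ", motif_id, ": matrix rows must have 4 columns"))
    }
    mat <- t(do.call(rbind, vals)) # 4 x width
    rownames(mat) <- c("A", "C", "G", "T")
    sums <- colSums(mat)
    if (any(abs(sums - 1) > 1e-3)) {
      k <- which(abs(sums - 1) > 1e-3)[1L]
      abort(sprintf(
        "motif %s: probability column %d sums to %.4g (must be 1 +/- 1e-3)",
        motif_id, k, sums[k]
      ))
    }
    mat <- sweep(mat, 2L, sums, "/")
    motifs[[i]] <- list(motif_id = motif_id, width = w, mat = mat)
  }
  structure(motifs, class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif_library> ", length(x), " motifs, widths ",
      paste(range(vapply(x, function(m) as.integer(m$width), integer(1))),
            collapse = "-"), "\n",
      sep = "")
  invisible(x)
}

#' Write a motif library in MEME minimal format
#'
#' @param motifs A `motif_library` (or plain list of motifs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_database <- function(motifs, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (m in motifs) {
    out <- c(out,
             paste("MOTIF", m$motif_id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     m$width),
             apply(t(m$mat), 1L, function(r) paste(sprintf("%.6f", r),
                                                   collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
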