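# Cluster3-compatible CDT/GTR export for Java TreeView.

#' Write CDT and GTR files for Java TreeView
#'
#' The CDT is tab-separated with header `GID`, `NAME`, `GWEIGHT` followed by
#' the streak columns, rows in dendrogram order with Cluster3-style ids
#' (`GENE<i>X`, 0-based original row index). The GTR lists the merges in
#' order (`NODE<j>X`, two children, height rescaled to `[-1, 1]` as
#' `1 - 2 * h / h_max`, so values are nonincreasing down the file). Values
#' are printed with enough digits that re-reading the CDT reproduces the
#' matrix exactly.
#'
#' @param kinetics The kinetics tibble that was clustered.
#' @param clust The `telka_clust` computed on it.
#' @param prefix Output path prefix; writes `<prefix>.cdt` and
#'   `<prefix>.gtr`.
#' @return Invisibly, the two paths.
#' @export
write_cdt_gtr <- function(kinetics, clust, prefix) {
  stopifnot(inherits(clust, "telka_clust"))
  m <- kinetics_to_matrix(kinetics)
  hc <- clust$hclust
  if (nrow(m) != nrow(clust$labels) ||
      !identical(rownames(m), clust$labels$mutant)) {
    abort("clustering was not computed on this kinetics table",
          class = "telka_error_input")
  }
  num <- function(x) sprintf("%.17g", x)
  gid <- function(i) sprintf("GENE%dX", i - 1L)      # 0-based ids
  nid <- function(j) sprintf("NODE%dX", j)
  cdt_path <- paste0(prefix, ".cdt")
  gtr_path <- paste0(prefix, ".gtr")

  merge <- hc$merge
  h <- hc$height
  h_max <- max(h)
  scaled <- if (h_max > 0) 1 - 2 * h / h_max else rep(1, length(h))
  child <- function(x) if (x < 0) gid(-x) else nid(x)
  gtr <- vapply(seq_len(nrow(merge)), function(j) {
    paste(nid(j), child(merge[j, 1]), child(merge[j, 2]), num(scaled[j]),
          sep = "\t")
  }, character(1))
  writeLines(gtr, gtr_path)

  ord <- hc$order
  header <- paste(c("GID", "NAME", "GWEIGHT", colnames(m)), collapse = "\t")
  body <- vapply(ord, function(i) {
    paste(c(gid(i), rownames(m)[i], "1", num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), cdt_path)
  invisible(c(cdt = cdt_path, gtr = gtr_path))
}

#' Read a CDT file back into a kinetics tibble
#'
#' Parses the dialect written by [write_cdt_gtr()] (and plain Cluster3
#' CDTs without an EWEIGHT row), returning rows in original order if the
#' GID encodes it, else in file order.
#'
#' @param path A `.cdt` file.
#' @return A kinetics tibble: `mutant` + data columns.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (!identical(header[1:3], c("GID", "NAME", "GWEIGHT"))) {
    abort("not a recognised CDT header", class = "telka_error_io")
  }
  data_cols <- header[-(1:3)]
  body <- fields[-1]
  body <- body[!vapply(body, function(f) f[1] %in% c("EWEIGHT", "AID"),
                       logical(1))]
  vals <- do.call(rbind, lapply(body, function(f) as.numeric(f[-(1:3)])))
  mutant <- vapply(body, `[[`, character(1), 2)
  gidx <- suppressWarnings(
    as.integer(sub("^GENE([0-9]+)X$", "\\1",
                   vapply(body, `[[`, character(1), 1))))
  out <- dplyr::bind_cols(tibble(mutant = mutant),
                          as_tibble(`colnames<-`(vals, data_cols)))
  if (!anyNA(gidx) && length(unique(gidx)) == length(gidx)) {
    out <- out[order(gidx), ]
  }
  out
}
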