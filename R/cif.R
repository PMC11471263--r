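## Focused mmCIF reader: tokenizes a CIF file and materialises requested
## categories (e.g. atom_site, entity_poly) as tibbles.  Handles loop_ and
## key-value presentation, quoted values, comments and semicolon text
## blocks — the subset of the CIF grammar that structure files use.

cif_tokenize <- function(lines) {
  tokens <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {
      val <- sub("^;", "", ln)
      i <- i + 1L
      block <- character()
      while (i <= n && !startsWith(lines[i], ";")) {
        block <- c(block, lines[i]); i <- i + 1L
      }
      tokens[[length(tokens) + 1L]] <- paste(c(val, block), collapse = "\n")
      i <- i + 1L
      next
    }
    m <- gregexpr("('[^']*'|\"[^\"]*\"|#.*$|\\S+)", ln)[[1]]
    if (m[1] != -1L) {
      toks <- regmatches(ln, list(m))[[1]]
      for (tk in toks) {
        if (startsWith(tk, "#")) break
        if ((startsWith(tk, "'") && endsWith(tk, "'") && nchar(tk) >= 2L) ||
            (startsWith(tk, "\"") && endsWith(tk, "\"") && nchar(tk) >= 2L)) {
          tk <- substr(tk, 2L, nchar(tk) - 1L)
          attr(tk, "quoted") <- TRUE
        }
        tokens[[length(tokens) + 1L]] <- tk
      }
    }
    i <- i + 1L
  }
  tokens
}

is_tag <- function(tk) is.null(attr(tk, "quoted")) && startsWith(tk, "_")
is_reserved <- function(tk) {
  is.null(attr(tk, "quoted")) &&
    grepl("^(data_|loop_$|stop_$|global_$|save_)", tk)
}

#' @noRd
parse_cif <- function(path, categories = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  toks <- cif_tokenize(lines)
  out <- list()
  i <- 1L
  n <- length(toks)
  add_value <- function(cat, item, values) {
    tbl <- out[[cat]] %||% list()
    tbl[[item]] <- values
    out[[cat]] <<- tbl
  }
  while (i <= n) {
    tk <- toks[[i]]
    if (is.null(attr(tk, "quoted")) && identical(tk, "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= n && is_tag(toks[[i]])) {
        tags <- c(tags, toks[[i]]); i <- i + 1L
      }
      vals <- list()
      while (i <= n && !is_tag(toks[[i]]) && !is_reserved(toks[[i]])) {
        vals[[length(vals) + 1L]] <- as.character(toks[[i]])
        i <- i + 1L
      }
      if (length(tags) == 0L) next
      if (length(vals) %% length(tags) != 0L) {
        abort(sprintf("mmCIF format error in %s: loop_ with %d tags has %d values",
                      path, length(tags), length(vals)))
      }
      vmat <- matrix(unlist(vals), ncol = length(tags), byrow = TRUE)
      for (k in seq_along(tags)) {
        parts <- strsplit(sub("^_", "", tags[k]), ".", fixed = TRUE)[[1]]
        cat_name <- parts[1]; item <- paste(parts[-1], collapse = ".")
        if (is.null(categories) || cat_name %in% categories) {
          add_value(cat_name, item, vmat[, k])
        }
      }
      next
    } else if (is_tag(tk)) {
      if (i + 1L > n) abort(sprintf("mmCIF format error in %s: dangling tag %s", path, tk))
      parts <- strsplit(sub("^_", "", tk), ".", fixed = TRUE)[[1]]
      cat_name <- parts[1]; item <- paste(parts[-1], collapse = ".")
      if (is.null(categories) || cat_name %in% categories) {
        add_value(cat_name, item, as.character(toks[[i + 1L]]))
      }
      i <- i + 2L
      next
    }
    i <- i + 1L
  }
  lapply(out, function(tbl) {
    len <- max(lengths(tbl))
    as_tibble(lapply(tbl, function(v) if (length(v) == len) v else rep(v, length.out = len)))
  })
}
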