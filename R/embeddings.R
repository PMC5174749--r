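## Vocabulary construction, word2vec-text channel loading, and assembly of
## the multichannel lookup tensor D (c channels x v vocab x d dims).

#' Build the task vocabulary
#'
#' Collects all token symbols seen in the training instances and prepends the
#' reserved specials: `<PAD>` (always index 1, embedding frozen at zero),
#' `<UNK>` (index 2, target of out-of-vocabulary tokens at test time), and
#' the blinding symbols `Entity1`, `Entity2`, `EntityOther`. Corpus tokens
#' are sorted so the mapping is reproducible.
#'
#' @param instances list of `mccnn_instance` objects (or a character vector
#'   of tokens).
#' @return An object of class `mccnn_vocab`: list with `symbols` (character
#'   vector, indices dense in `1:v`) and `size`.
#' @export
build_vocab <- function(instances) {
  tokens <- if (is.character(instances)) instances
            else unlist(lapply(instances, function(i) i$tokens))
  words <- sort(setdiff(unique(tokens), .SPECIALS))
  structure(list(symbols = c(.SPECIALS, words),
                 size = length(.SPECIALS) + length(words)),
            class = "mccnn_vocab")
}

#' @export
print.mccnn_vocab <- function(x, ...) {
  cat(sprintf("<mccnn_vocab: %d symbols (%d specials)>\n", x$size,
              length(.SPECIALS)))
  invisible(x)
}

#' Encode tokens as vocabulary indices
#'
#' @param tokens character vector of token symbols.
#' @param vocab an `mccnn_vocab`.
#' @return Integer indices; tokens absent from the vocabulary map to the
#'   `<UNK>` index.
#' @export
encode_tokens <- function(tokens, vocab) {
  idx <- match(tokens, vocab$symbols)
  idx[is.na(idx)] <- .UNK_INDEX
  idx
}

#' Decode vocabulary indices back to token symbols
#'
#' @param indices integer indices in `1:v`.
#' @param vocab an `mccnn_vocab`.
#' @return Character vector of symbols.
#' @export
decode_indices <- function(indices, vocab) {
  if (any(indices < 1L | indices > vocab$size)) {
    stop_validation("index outside vocabulary range [1, %d]", vocab$size)
  }
  vocab$symbols[indices]
}

#' Load one embedding channel from a word2vec text file
#'
#' Reads a `word v1 ... vd` table (an optional `count dim` header line is
#' tolerated) and aligns it to the task vocabulary. Vocabulary words present
#' in the table get their stored vectors; absent words — and all special
#' symbols except `<PAD>`, which are artificial and never looked up — get
#' i.i.d. uniform components in `[-0.25, 0.25]` drawn from `seed`. `<PAD>`
#' is the zero vector.
#'
#' @param path word2vec text file.
#' @param vocab an `mccnn_vocab`.
#' @param d embedding dimension; must match the file rows.
#' @param seed integer seed for the out-of-table initialization.
#' @param name channel name; defaults to the file name.
#' @return Class `embedding_channel`: list with `name`, `vectors` (`v x d`
#'   matrix aligned to `vocab`), and `coverage` (count of non-special
#'   vocabulary words found in the table).
#' @export
load_channel <- function(path, vocab, d, seed = 1L, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
    if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
      lines <- lines[-1]  # header "count dim"
    }
  }
  table_words <- character(length(lines))
  table_vecs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (length(vals) != d || anyNA(vals)) {
      stop_validation("'%s' row %d ('%s'): expected %d numeric components",
                      path, i, f[1], d)
    }
    table_words[i] <- f[1]
    table_vecs[[i]] <- vals
  }
  names(table_vecs) <- table_words
  mat <- matrix(0, nrow = vocab$size, ncol = d)
  lookupable <- !(vocab$symbols %in% .SPECIALS)
  hit <- lookupable & vocab$symbols %in% table_words
  with_seed(seed, {
    for (i in seq_len(vocab$size)) {
      if (i == .PAD_INDEX) next              # PAD stays zero
      if (hit[i]) mat[i, ] <- table_vecs[[vocab$symbols[i]]]
      else mat[i, ] <- stats::runif(d, -0.25, 0.25)
    }
  })
  structure(list(name = name, vectors = mat, coverage = sum(hit)),
            class = "embedding_channel")
}

#' Assemble channels into a multichannel embedding
#'
#' Stacks `c` aligned channels into the lookup tensor `D` (stored as a list
#' of `v x d` matrices, one slice per channel, in the given order).
#'
#' @param channels list of `embedding_channel` objects with identical
#'   dimensions and vocabulary alignment.
#' @return Class `mc_embedding`: list with `D`, `channels` (names),
#'   `coverage`, and dimensions `c`, `v`, `d`.
#' @export
assemble_channels <- function(channels) {
  if (!length(channels)) stop_validation("need at least one channel")
  dims <- vapply(channels, function(ch) dim(ch$vectors), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_validation("channels disagree on dimensions (%s)",
                    paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  }
  structure(list(D = lapply(channels, function(ch) ch$vectors),
                 channels = vapply(channels, function(ch) ch$name, character(1)),
                 coverage = vapply(channels, function(ch) ch$coverage, numeric(1)),
                 c = length(channels), v = dims[1, 1], d = dims[2, 1]),
            class = "mc_embedding")
}

#' @export
print.mc_embedding <- function(x, ...) {
  cat(sprintf("<mc_embedding: %d channel(s), v=%d, d=%d>\n", x$c, x$v, x$d))
  invisible(x)
}

#' Write an embedding table in word2vec text format
#'
#' @param words character vector of words.
#' @param vectors numeric matrix, one row per word.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_channel <- function(words, vectors, path) {
  stopifnot(length(words) == nrow(vectors))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(words), ncol(vectors)), con)
  for (i in seq_along(words)) {
    writeLines(paste(words[i],
                     paste(sprintf("%.17g", vectors[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
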