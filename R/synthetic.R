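## Synthetic DDI-style corpora with known structure: each positive pair's
## class is carried by a single cue token placed directly between its two
## entities, so the label is recoverable by any filter bank whose smallest
## window covers a trigram, and the Bayes-optimal micro-F on decoy-free
## corpora is 100. Decoy sentences exercise the two noise-filter rules.

#' Synthetic corpus configuration
#'
#' The generator emulates the DDI annotation scheme: sentences with 2-5 drug
#' mentions, gold labels over four interaction classes plus `negative`, and
#' two kinds of decoy noise — repeated-name pairs (rule 1 fodder) and
#' comma/"or" coordinate lists (rule 2 fodder). Cue phrases are single
#' tokens placed strictly between the target entities so that every window
#' size can see them; each class owns two interchangeable cue tokens, which
#' also makes within-class cue clustering measurable in fabricated channels.
#'
#' @param n_sentences number of sentences to generate.
#' @param cues named list mapping each positive class to its cue tokens.
#' @param entities_range integer range of entities per sentence.
#' @param filler_vocab number of distinct filler word types.
#' @param sentence_length range of filler-token counts per sentence (the
#'   entity/cue block is inserted on top).
#' @param p_same_name probability that a sentence is a repeated-name decoy.
#' @param p_coordinate probability that a sentence is a coordinate-list
#'   decoy.
#' @param p_negative probability that a normal sentence's target pair is
#'   negative (remaining mass is spread uniformly over the positive
#'   classes).
#' @param channels list describing fabricated embedding channels:
#'   `coverage` (vocabulary fraction each channel covers) and `d`
#'   (dimension).
#' @param seed master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sentences = 200L,
                         cues = list(advice = c("recommended", "advised"),
                                     effect = c("potentiates", "exacerbates"),
                                     mechanism = c("inhibits", "accelerates"),
                                     int = c("interacts", "reacts")),
                         entities_range = c(2L, 5L),
                         filler_vocab = 40L,
                         sentence_length = c(8L, 16L),
                         p_same_name = 0.1, p_coordinate = 0.1,
                         p_negative = 0.2,
                         channels = list(coverage = c(1.0, 0.7), d = 16L),
                         seed = 1L) {
  stopifnot(p_same_name >= 0, p_coordinate >= 0, p_same_name + p_coordinate <= 1,
            p_negative >= 0, p_negative <= 1,
            entities_range[1] >= 2L, entities_range[2] >= entities_range[1],
            sentence_length[1] >= entities_range[2] + 2L, filler_vocab >= 5L,
            all(channels$coverage > 0), all(channels$coverage <= 1))
  structure(list(n_sentences = as.integer(n_sentences), cues = cues,
                 entities_range = as.integer(entities_range),
                 filler_vocab = as.integer(filler_vocab),
                 sentence_length = as.integer(sentence_length),
                 p_same_name = p_same_name, p_coordinate = p_coordinate,
                 p_negative = p_negative, channels = channels,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## sample() treats a length-1 numeric x as 1:x; this keeps set semantics
.resample <- function(x, size = 1L) x[sample.int(length(x), size)]

.fillers <- function(config) sprintf("w%02d", seq_len(config$filler_vocab))
.drug_pool <- function() sprintf("drug%02d", 1:30)

.make_sentence <- function(tokens, entity_positions, entity_ids, sid, pairs) {
  ## entity_positions: token indices; token strings have no internal spaces
  starts <- integer(length(tokens)); ends <- integer(length(tokens))
  pos <- 0L
  for (i in seq_along(tokens)) {
    starts[i] <- pos
    ends[i] <- pos + nchar(tokens[i]) - 1L
    pos <- ends[i] + 2L   # single space between tokens
  }
  text <- paste(tokens, collapse = " ")
  entities <- do.call(rbind, lapply(seq_along(entity_positions), function(j) {
    p <- entity_positions[j]
    entity_mention(entity_ids[j], tokens[p], starts[p], ends[p], "drug")
  }))
  annotated_sentence(sid, text, entities, pairs)
}

.all_pairs <- function(entity_ids, positions, labels_by_target = NULL,
                       target = NULL, target_label = "negative") {
  ord <- order(positions)
  ids <- entity_ids[ord]
  n <- length(ids)
  if (n < 2L) return(.empty_pairs())
  idx <- utils::combn(n, 2L)
  out <- .empty_pairs()
  for (k in seq_len(ncol(idx))) {
    a <- ids[idx[1, k]]; b <- ids[idx[2, k]]
    lab <- if (!is.null(target) && setequal(c(a, b), target)) target_label
           else "negative"
    out <- rbind(out, gold_pair(a, b, lab))
  }
  out
}

#' Generate a synthetic annotated corpus
#'
#' Draws sentences of three kinds: normal sentences whose single target pair
#' carries a class cue token directly between its entities (or a filler
#' token for negative pairs), repeated-name decoys, and coordinate-list
#' decoys. All candidate pairs not designated as the target are `negative`.
#' The manifest records, for every candidate pair, its gold label and which
#' filter rule (if any) should remove it.
#'
#' @param config a [synth_config()].
#' @return List with `sentences` (list of [annotated_sentence]), `manifest`
#'   (`data.frame` with `sentence_id, e1, e2, label, removable`), and
#'   `config`. Deterministic given `config$seed`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fillers <- .fillers(config)
  pool <- .drug_pool()
  positives <- names(config$cues)
  with_seed(config$seed, {
    sentences <- vector("list", config$n_sentences)
    manifest <- list()
    for (s in seq_len(config$n_sentences)) {
      sid <- sprintf("s%04d", s)
      u <- stats::runif(1)
      kind <- if (u < config$p_coordinate) "coordinate"
              else if (u < config$p_coordinate + config$p_same_name) "same_name"
              else "normal"
      L <- .resample(config$sentence_length[1]:config$sentence_length[2])
      base <- sample(fillers, L, replace = TRUE)
      if (kind == "normal") {
        n_e <- .resample(config$entities_range[1]:config$entities_range[2])
        names_e <- sample(pool, n_e)
        ids_e <- sprintf("%s.e%d", sid, seq_len(n_e) - 1L)
        neg <- stats::runif(1) < config$p_negative
        label <- if (neg) "negative" else sample(positives, 1L)
        mid <- if (neg) .resample(fillers) else .resample(config$cues[[label]])
        ## target block E1 cue E2 replaces three consecutive filler slots
        slot <- .resample(seq_len(L - 2L))
        tokens <- base
        tokens[slot:(slot + 2L)] <- c(names_e[1], mid, names_e[2])
        positions <- c(slot, slot + 2L)
        ## remaining entities occupy filler slots outside the block
        if (n_e > 2L) {
          free <- setdiff(seq_len(L), slot:(slot + 2L))
          extra <- sample(free, n_e - 2L)
          tokens[extra] <- names_e[3:n_e]
          positions <- c(positions, extra)
        }
        pairs <- .all_pairs(ids_e, positions, target = ids_e[1:2],
                            target_label = label)
        sentences[[s]] <- .make_sentence(tokens, positions, ids_e, sid, pairs)
        pairs$removable <- "none"
      } else if (kind == "same_name") {
        nm <- sample(pool, 1L)
        ids_e <- sprintf("%s.e%d", sid, 0:1)
        slots <- sort(sample(seq_len(L), 2L))
        tokens <- base
        tokens[slots] <- nm
        pairs <- gold_pair(ids_e[1], ids_e[2], "negative")
        sentences[[s]] <- .make_sentence(tokens, slots, ids_e, sid, pairs)
        pairs$removable <- "rule1"
      } else {
        n_e <- .resample(max(3L, config$entities_range[1]):config$entities_range[2])
        names_e <- sample(pool, n_e)
        ids_e <- sprintf("%s.e%d", sid, seq_len(n_e) - 1L)
        ## coordinate list: E1 , E2 , ... or En, inserted mid-sentence
        list_tokens <- character(0)
        for (j in seq_len(n_e)) {
          list_tokens <- c(list_tokens, names_e[j],
                           if (j < n_e - 1L) "," else if (j == n_e - 1L) "or")
        }
        cut <- .resample(seq_len(L - 1L))
        tokens <- c(base[seq_len(cut)], list_tokens, base[(cut + 1L):L])
        positions <- cut + 2L * seq_len(n_e) - 1L
        pairs <- .all_pairs(ids_e, positions)
        sentences[[s]] <- .make_sentence(tokens, positions, ids_e, sid, pairs)
        pairs$removable <- "rule2"
      }
      pairs$sentence_id <- sid
      manifest[[s]] <- pairs
    }
    manifest <- do.call(rbind, manifest)
    manifest <- manifest[, c("sentence_id", "e1", "e2", "label", "removable")]
    rownames(manifest) <- NULL
    list(sentences = sentences, manifest = manifest, config = config)
  })
}

#' Fabricate word-embedding channels for a synthetic corpus
#'
#' Builds one word2vec-style table per configured channel over the corpus
#' word types. Each channel covers its configured fraction of the
#' vocabulary (channels beyond the first drop a random remainder, emulating
#' partial-coverage pretrained tables). Cue tokens receive class-clustered
#' vectors — cues of the same class sit closer in cosine than cues of
#' different classes — so the fabricated channels are informative about the
#' label, as pretrained embeddings are about interaction verbs.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir directory to write `channel<k>.txt` files into, or `NULL` to
#'   skip writing.
#' @return List of channels, each with `words`, `vectors` and (if written)
#'   `path`.
#' @export
generate_channels <- function(corpus, dir = NULL) {
  config <- corpus$config
  words <- sort(unique(unlist(lapply(corpus$sentences, function(s) {
    tokenize_sentence(s)$token
  }))))
  cues <- config$cues
  d <- config$channels$d
  with_seed(derive_seed(config$seed, 2L), {
    class_centers <- lapply(seq_along(cues), function(i) stats::rnorm(d))
    names(class_centers) <- names(cues)
    out <- vector("list", length(config$channels$coverage))
    for (k in seq_along(config$channels$coverage)) {
      frac <- config$channels$coverage[k]
      covered <- if (frac >= 1) words else sample(words, ceiling(frac * length(words)))
      covered <- sort(covered)
      mat <- matrix(stats::runif(length(covered) * d, -0.25, 0.25),
                    length(covered), d)
      rownames(mat) <- covered
      for (cl in names(cues)) {
        for (cue in intersect(cues[[cl]], covered)) {
          vec <- class_centers[[cl]] + stats::rnorm(d, 0, 0.3)
          mat[cue, ] <- 0.25 * vec / sqrt(sum(vec^2))
        }
      }
      ch <- list(words = covered, vectors = mat)
      if (!is.null(dir)) {
        path <- file.path(dir, sprintf("channel%d.txt", k))
        write_channel(covered, mat, path)
        ch$path <- path
      }
      out[[k]] <- ch
    }
    out
  })
}
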