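# Fixture sentences built in code (offsets computed, never hardcoded) and
# independent brute-force oracles kept deliberately separate from the
# package's vectorized implementations.

# locate the n-th occurrence of a word in a sentence and return the 0-based
# inclusive char offsets
find_span <- function(text, word, occurrence = 1L) {
  hits <- gregexpr(word, text, fixed = TRUE)[[1]]
  start <- hits[occurrence]
  c(start - 1L, start + nchar(word) - 2L)
}

mention_at <- function(id, text, word, occurrence = 1L, etype = "drug") {
  sp <- find_span(text, word, occurrence)
  entity_mention(id, word, sp[1], sp[2], etype)
}

# three-drug caution sentence: 3 entities, 3 candidate pairs, none filtered
caution_sentence <- function() {
  text <- paste("Caution should be exercised when administering nabumetone",
                "with warfarin since interactions have been seen with other NSAIDs")
  annotated_sentence("fix.s1", text,
    rbind(mention_at("fix.s1.e0", text, "nabumetone"),
          mention_at("fix.s1.e1", text, "warfarin"),
          mention_at("fix.s1.e2", text, "NSAIDs")),
    rbind(gold_pair("fix.s1.e0", "fix.s1.e1", "mechanism"),
          gold_pair("fix.s1.e0", "fix.s1.e2", "negative"),
          gold_pair("fix.s1.e1", "fix.s1.e2", "negative")))
}

# repeated-name pair: "Anesthetics ... anesthetics" differs only in case
same_name_sentence <- function() {
  text <- paste("Anesthetics, general: exaggeration of the hypotension",
                "induced by general anesthetics")
  annotated_sentence("fix.s2", text,
    rbind(mention_at("fix.s2.e0", text, "Anesthetics"),
          mention_at("fix.s2.e1", text, "anesthetics")),
    gold_pair("fix.s2.e0", "fix.s2.e1", "negative"))
}

# five entities in a comma/or coordinate list; every pair is noise
coordinate_sentence <- function() {
  text <- paste("To minimize CNS depression and possible potentiation,",
                "barbiturates, antihistamines, narcotics, hypotensive agents",
                "or phenothiazines should be used with caution")
  ents <- rbind(mention_at("fix.s3.e0", text, "barbiturates"),
                mention_at("fix.s3.e1", text, "antihistamines"),
                mention_at("fix.s3.e2", text, "narcotics"),
                mention_at("fix.s3.e3", text, "hypotensive agents"),
                mention_at("fix.s3.e4", text, "phenothiazines"))
  pairs <- do.call(rbind, apply(utils::combn(5, 2), 2, function(ij) {
    gold_pair(ents$id[ij[1]], ents$id[ij[2]], "negative")
  }))
  annotated_sentence("fix.s3", text, ents, pairs)
}

# -- independent oracles ----------------------------------------------------

# Eq.-style convolution: four nested loops over positions, channels, window
# offsets and embedding dimensions
conv_oracle <- function(V, W, b, relu = TRUE) {
  cc <- length(V); h <- dim(W)[2]; d <- ncol(V[[1]]); N <- nrow(V[[1]])
  P <- N - h + 1
  out <- numeric(P)
  for (k in seq_len(P)) {
    acc <- 0
    for (i in seq_len(cc)) {
      for (r in seq_len(h)) {
        for (j in seq_len(d)) {
          acc <- acc + V[[i]][k + r - 1, j] * W[i, r, j]
        }
      }
    }
    out[k] <- if (relu) max(acc + b, 0) else acc + b
  }
  out
}

# reference metrics by explicit counting, one instance at a time
score_oracle <- function(gold, pred, positive) {
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(P = p, R = r, F = f)
  }
  tp <- fp <- fn <- 0
  btp <- bfp <- bfn <- 0
  for (i in seq_along(gold)) {
    g <- gold[i]; q <- pred[i]
    if (g %in% positive && q == g) tp <- tp + 1
    if (q %in% positive && q != g) fp <- fp + 1
    if (g %in% positive && q != g) fn <- fn + 1
    gp <- g %in% positive; qp <- q %in% positive
    if (gp && qp) btp <- btp + 1
    if (qp && !gp) bfp <- bfp + 1
    if (gp && !qp) bfn <- bfn + 1
  }
  list(micro = prf(tp, fp, fn), dec = prf(btp, bfp, bfn))
}

# random embedding channels aligned to a vocab, for model-level tests
random_embedding <- function(v, d, cc, seed = 1) {
  withr::with_seed(seed, {
    chans <- lapply(seq_len(cc), function(i) {
      structure(list(name = paste0("ch", i),
                     vectors = rbind(0, matrix(stats::rnorm((v - 1) * d, 0, 0.2),
                                               v - 1, d)),
                     coverage = 0),
                class = "embedding_channel")
    })
    assemble_channels(chans)
  })
}

# a small decoy-free cue corpus plus its channels and kept instances
cue_dataset <- function(n_sentences, seed, entities = c(2L, 2L)) {
  cfg <- synth_config(n_sentences = n_sentences, entities_range = entities,
                      p_same_name = 0, p_coordinate = 0, seed = seed)
  corpus <- generate_corpus(cfg)
  list(corpus = corpus, kept = build_dataset(corpus$sentences)$kept)
}
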