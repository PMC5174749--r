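## Preprocessing: tokenization with entity collapsing, candidate-pair
## enumeration, entity blinding, and the two noise-filter rules.

.split_segment <- function(txt, offset0) {
  ## split a non-entity text segment on whitespace and punctuation
  ## boundaries; punctuation marks become single-character tokens, so token
  ## spans partition the segment's non-whitespace characters
  m <- gregexpr("[^[:space:][:punct:]]+|[[:punct:]]", txt)[[1]]
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  data.frame(token = substring(txt, m, m + len - 1L),
             start = offset0 + m - 1L,
             end = offset0 + m + len - 2L,
             entity_id = NA_character_, stringsAsFactors = FALSE)
}

#' Tokenize an annotated sentence
#'
#' Splits the sentence text on whitespace and punctuation boundaries, except
#' that each entity mention — multiword or not — is collapsed into a single
#' token covering its whole annotated span. Token spans are 0-based inclusive
#' character offsets and partition the non-whitespace text.
#'
#' @param sentence an [annotated_sentence].
#' @return A `data.frame` with columns `token, start, end, entity_id`
#'   (`entity_id` is `NA` for non-entity tokens), in document order.
#'   Overlapping entity spans are a validation error.
#' @export
tokenize_sentence <- function(sentence) {
  validate_sentence(sentence)
  e <- sentence$entities
  e <- e[order(e$char_start, e$char_end), , drop = FALSE]
  if (nrow(e) > 1L && any(e$char_start[-1] <= e$char_end[-nrow(e)])) {
    i <- which(e$char_start[-1] <= e$char_end[-nrow(e)])[1]
    stop_validation("sentence '%s': entity '%s' overlaps the span of entity '%s'",
                    sentence$id, e$id[i + 1L], e$id[i])
  }
  out <- list()
  cursor <- 0L
  for (i in seq_len(nrow(e))) {
    if (e$char_start[i] > cursor) {
      seg <- substr(sentence$text, cursor + 1L, e$char_start[i])
      out[[length(out) + 1L]] <- .split_segment(seg, cursor)
    }
    out[[length(out) + 1L]] <- data.frame(
      token = e$surface[i], start = e$char_start[i], end = e$char_end[i],
      entity_id = e$id[i], stringsAsFactors = FALSE)
    cursor <- e$char_end[i] + 1L
  }
  n <- nchar(sentence$text)
  if (cursor < n) {
    out[[length(out) + 1L]] <- .split_segment(
      substr(sentence$text, cursor + 1L, n), cursor)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      entity_id = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate candidate entity pairs
#'
#' With `n` entities in a sentence, all `choose(n, 2)` unordered pairs are
#' candidates; the first member of each pair is the entity occurring earlier
#' in the text.
#'
#' @param sentence an [annotated_sentence].
#' @return `data.frame` with columns `e1, e2` (entity ids in document order),
#'   ordered by position of `e1` then `e2`; zero rows for `n < 2`.
#' @export
enumerate_pairs <- function(sentence) {
  e <- sentence$entities
  e <- e[order(e$char_start, e$char_end), , drop = FALSE]
  n <- nrow(e)
  if (n < 2L) {
    return(data.frame(e1 = character(), e2 = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  data.frame(e1 = e$id[idx[1, ]], e2 = e$id[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Blind a candidate pair
#'
#' Replaces the two target entity tokens with `Entity1` (the one occurring
#' first) and `Entity2`, and every non-target entity token with
#' `EntityOther`. Non-entity tokens are untouched, so blinding preserves the
#' token count and is independent of the pair's label.
#'
#' @param tokens token table from [tokenize_sentence()].
#' @param e1,e2 target entity ids (order irrelevant; document order is
#'   restored internally).
#' @return Character vector of blinded token symbols.
#' @export
blind_pair <- function(tokens, e1, e2) {
  p1 <- which(!is.na(tokens$entity_id) & tokens$entity_id == e1)
  p2 <- which(!is.na(tokens$entity_id) & tokens$entity_id == e2)
  if (length(p1) != 1L || length(p2) != 1L) {
    stop_validation("target entity '%s' or '%s' not found as a single token",
                    e1, e2)
  }
  out <- tokens$token
  out[!is.na(tokens$entity_id)] <- .ENTITY_OTHER
  if (p1 < p2) {
    out[p1] <- .ENTITY1; out[p2] <- .ENTITY2
  } else {
    out[p2] <- .ENTITY1; out[p1] <- .ENTITY2
  }
  out
}

.initials <- function(x) {
  words <- strsplit(x, "[[:space:]-]+")[[1]]
  words <- words[nzchar(words)]
  paste(substr(words, 1L, 1L), collapse = "")
}

#' Noise filter rule 1: same name or abbreviation
#'
#' Flags a candidate pair whose two mentions refer to the same thing: equal
#' surface forms (case-folded), a parenthesized short form immediately
#' following the long form, or one surface being the initial-letter acronym
#' of the other's words. Such pairs cannot encode an interaction and are
#' removed as noise.
#'
#' @param sentence the source [annotated_sentence].
#' @param e1,e2 entity ids of the candidate pair.
#' @return `TRUE` if the pair should be removed.
#' @export
rule1_same_name <- function(sentence, e1, e2) {
  ent <- sentence$entities
  a <- ent[ent$id == e1, ]
  b <- ent[ent$id == e2, ]
  if (!nrow(a) || !nrow(b)) stop_validation("unknown entity id in rule 1")
  sa <- tolower(trimws(a$surface)); sb <- tolower(trimws(b$surface))
  if (identical(sa, sb)) return(TRUE)
  ## "long form (SHORT)" pattern, either order
  paren <- function(first, second) {
    gap <- substr(sentence$text, first$char_end + 2L, second$char_start)
    after <- substr(sentence$text, second$char_end + 2L,
                    min(second$char_end + 3L, nchar(sentence$text)))
    grepl("^[[:space:]]*\\($", gap) && grepl("^[[:space:]]*\\)", after)
  }
  lo <- if (a$char_start <= b$char_start) a else b
  hi <- if (a$char_start <= b$char_start) b else a
  if (paren(lo, hi)) return(TRUE)
  ## acronym: initial letters of the multiword mention spell the other
  if (identical(tolower(.initials(a$surface)), sb) && nchar(sb) > 1L) return(TRUE)
  if (identical(tolower(.initials(b$surface)), sa) && nchar(sa) > 1L) return(TRUE)
  FALSE
}

#' Noise filter rule 2: coordinate structure
#'
#' Flags a candidate pair that sits inside a comma/"and"/"or" list of
#' entities: every token strictly between `Entity1` and `Entity2` in the
#' blinded sequence belongs to `{",", "and", "or", EntityOther}` and at least
#' one separator (comma, "and", "or") is present. Entities that merely sit
#' next to each other (nothing between) are not coordinate.
#'
#' @param blinded character vector from [blind_pair()].
#' @return `TRUE` if the pair should be removed.
#' @export
rule2_coordinate <- function(blinded) {
  p1 <- which(blinded == .ENTITY1)
  p2 <- which(blinded == .ENTITY2)
  if (length(p1) != 1L || length(p2) != 1L) {
    stop_validation("blinded sequence must contain exactly one Entity1 and one Entity2")
  }
  if (p2 - p1 < 2L) return(FALSE)
  between <- blinded[(p1 + 1L):(p2 - 1L)]
  separators <- c(",", "and", "or")
  allowed <- c(separators, .ENTITY_OTHER)
  all(between %in% allowed) && any(between %in% separators)
}

.pair_label <- function(sentence, e1, e2) {
  p <- sentence$pairs
  hit <- (p$e1 == e1 & p$e2 == e2) | (p$e1 == e2 & p$e2 == e1)
  if (any(hit)) p$label[which(hit)[1]] else "negative"
}

#' Build a classification dataset from annotated sentences
#'
#' Tokenizes each sentence, enumerates all candidate pairs, blinds each pair,
#' attaches its gold label (pairs absent from the gold list are `negative`),
#' and optionally applies the two noise filters (rule 1 before rule 2). Kept
#' and removed instances partition the full candidate set.
#'
#' @param sentences list of [annotated_sentence] objects.
#' @param apply_filters apply rules 1-2? Disable for small corpora such as
#'   the PPI benchmarks, where filtering would cost too many instances.
#' @return A list with elements `kept` and `removed` (lists of instances;
#'   removed instances carry their `filtered` reason) and `report`, a
#'   `data.frame` of kept/removed counts per label.
#' @export
build_dataset <- function(sentences, apply_filters = TRUE) {
  kept <- list(); removed <- list()
  for (s in sentences) {
    toks <- tokenize_sentence(s)
    prs <- enumerate_pairs(s)
    for (i in seq_len(nrow(prs))) {
      e1 <- prs$e1[i]; e2 <- prs$e2[i]
      blinded <- blind_pair(toks, e1, e2)
      label <- .pair_label(s, e1, e2)
      reason <- "none"
      if (apply_filters) {
        if (rule1_same_name(s, e1, e2)) {
          reason <- "rule1"
        } else if (rule2_coordinate(blinded)) {
          reason <- "rule2"
        }
      }
      inst <- new_instance(s$id, e1, e2, blinded, label, reason)
      if (reason == "none") kept[[length(kept) + 1L]] <- inst
      else removed[[length(removed) + 1L]] <- inst
    }
  }
  labels <- sort(unique(c(instance_labels(kept), instance_labels(removed))))
  count <- function(instances, lab, why = NULL) {
    sum(vapply(instances, function(x) {
      x$label == lab && (is.null(why) || x$filtered == why)
    }, logical(1)))
  }
  report <- data.frame(
    label = labels,
    kept = vapply(labels, function(l) count(kept, l), numeric(1)),
    removed_rule1 = vapply(labels, function(l) count(removed, l, "rule1"), numeric(1)),
    removed_rule2 = vapply(labels, function(l) count(removed, l, "rule2"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(kept = kept, removed = removed, report = report)
}

#' Render a filter report as text
#'
#' @param report the `report` element of [build_dataset()].
#' @return Character vector of aligned report lines.
#' @export
format_filter_report <- function(report) {
  total <- data.frame(label = "total", kept = sum(report$kept),
                      removed_rule1 = sum(report$removed_rule1),
                      removed_rule2 = sum(report$removed_rule2))
  tab <- rbind(report, total)
  header <- sprintf("%-12s %8s %8s %8s %8s", "label", "kept", "rule1", "rule2", "before")
  rows <- sprintf("%-12s %8d %8d %8d %8d", tab$label, tab$kept,
                  tab$removed_rule1, tab$removed_rule2,
                  tab$kept + tab$removed_rule1 + tab$removed_rule2)
  c(header, rows)
}
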