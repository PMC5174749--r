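## Corpus readers/writers for the two standard relation-extraction XML
## dialects plus the package's own line-delimited instance format.

.parse_char_offset <- function(offset, sentence_id, entity_id) {
  spans <- strsplit(offset, ";", fixed = TRUE)[[1]]
  if (length(spans) > 1L) {
    warning(sprintf("sentence '%s': entity '%s' has a discontinuous charOffset '%s'; keeping first span",
                    sentence_id, entity_id, offset), call. = FALSE)
  }
  parts <- strsplit(spans[1], "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    stop_validation("sentence '%s': entity '%s' has malformed charOffset '%s'",
                    sentence_id, entity_id, offset)
  }
  as.integer(parts)
}

.sentence_from_xml <- function(node, dialect) {
  sid <- xml2::xml_attr(node, "id")
  text <- xml2::xml_attr(node, "text")
  ents <- xml2::xml_find_all(node, "./entity")
  entities <- .empty_entities()
  for (e in ents) {
    eid <- xml2::xml_attr(e, "id")
    off <- .parse_char_offset(xml2::xml_attr(e, "charOffset"), sid, eid)
    surface <- xml2::xml_attr(e, "text")
    if (off[1] < 0L || off[2] >= nchar(text)) {
      stop_validation("sentence '%s': entity '%s' charOffset outside sentence text",
                      sid, eid)
    }
    ## keep the substring at the first span as the effective surface when the
    ## annotated text covers a discontinuous mention
    span_text <- substr(text, off[1] + 1L, off[2] + 1L)
    if (!identical(span_text, surface)) surface <- span_text
    entities <- rbind(entities,
                      entity_mention(eid, surface, off[1], off[2],
                                     xml2::xml_attr(e, "type") %||% "entity"))
  }
  pnodes <- xml2::xml_find_all(node, "./pair")
  pairs <- .empty_pairs()
  for (p in pnodes) {
    if (dialect == "ddi2013") {
      flag <- tolower(xml2::xml_attr(p, "ddi"))
      type <- xml2::xml_attr(p, "type")
      label <- if (isTRUE(flag %in% c("true", "1"))) {
        if (is.na(type)) "positive" else type
      } else {
        "negative"
      }
    } else {
      flag <- tolower(xml2::xml_attr(p, "interaction"))
      label <- if (isTRUE(flag %in% c("true", "1"))) "positive" else "negative"
    }
    pairs <- rbind(pairs, gold_pair(xml2::xml_attr(p, "e1"),
                                    xml2::xml_attr(p, "e2"), label))
  }
  annotated_sentence(sid, text, entities, pairs)
}

#' Read a relation-extraction XML corpus
#'
#' Parses either the DDIExtraction 2013 dialect
#' (`document/sentence/entity/pair` with `id`, `charOffset`, `type`, `text`,
#' `e1`, `e2`, `ddi` attributes) or the unified PPI learning format (same
#' layout with a binary `interaction` attribute on pairs). Pair labels come
#' exclusively from `pair` elements: a pair flagged non-interacting, or
#' interacting without a `type`, maps to `negative` resp. `positive`. No
#' pairs are inferred from entity co-occurrence here.
#'
#' @param path path to an XML file.
#' @param dialect `"ddi2013"` or `"ppi_learning_format"`.
#' @return A list of [annotated_sentence] objects, one per `sentence`
#'   element in document order.
#' @export
read_relation_xml <- function(path, dialect = c("ddi2013", "ppi_learning_format")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("no such file: '%s'", path)
  doc <- tryCatch(xml2::read_xml(path, encoding = "UTF-8"),
                  error = function(e) {
                    stop_validation("malformed XML in '%s': %s", path,
                                    conditionMessage(e))
                  })
  nodes <- xml2::xml_find_all(doc, "//sentence")
  lapply(nodes, .sentence_from_xml, dialect = dialect)
}

#' Write a relation-extraction XML corpus
#'
#' Inverse of [read_relation_xml()]; all sentences are emitted under a single
#' `document` element. `read_relation_xml(write_relation_xml(x))` reproduces
#' the sentences field-for-field.
#'
#' @param sentences list of [annotated_sentence] objects.
#' @param path output file path.
#' @param dialect `"ddi2013"` or `"ppi_learning_format"`.
#' @return `path`, invisibly.
#' @export
write_relation_xml <- function(sentences, path,
                               dialect = c("ddi2013", "ppi_learning_format")) {
  dialect <- match.arg(dialect)
  root <- xml2::xml_new_root("corpus")
  doc <- xml2::xml_add_child(root, "document", id = "d0")
  for (s in sentences) {
    sn <- xml2::xml_add_child(doc, "sentence", id = s$id, text = s$text)
    e <- s$entities
    for (i in seq_len(nrow(e))) {
      xml2::xml_add_child(sn, "entity", id = e$id[i],
                          charOffset = sprintf("%d-%d", e$char_start[i], e$char_end[i]),
                          type = e$etype[i], text = e$surface[i])
    }
    p <- s$pairs
    for (i in seq_len(nrow(p))) {
      pid <- sprintf("%s.p%d", s$id, i - 1L)
      if (dialect == "ddi2013") {
        if (p$label[i] == "negative") {
          xml2::xml_add_child(sn, "pair", id = pid, e1 = p$e1[i], e2 = p$e2[i],
                              ddi = "false")
        } else {
          xml2::xml_add_child(sn, "pair", id = pid, e1 = p$e1[i], e2 = p$e2[i],
                              ddi = "true", type = p$label[i])
        }
      } else {
        xml2::xml_add_child(sn, "pair", id = pid, e1 = p$e1[i], e2 = p$e2[i],
                            interaction = if (p$label[i] == "negative") "false" else "true")
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Write instances in the internal line-delimited format
#'
#' One record per line, tab-separated:
#' `sentence_id, e1, e2, label, filtered, tokens` (tokens space-joined; token
#' symbols never contain whitespace). The first line records the label
#' vocabulary so that readers can validate labels.
#'
#' @param instances list of [new_instance()] objects sharing one label set.
#' @param path output path.
#' @param labels label vocabulary; defaults to the labels observed.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path, labels = NULL) {
  labels <- labels %||% sort(unique(instance_labels(instances)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#labels\t", paste(labels, collapse = ",")), con)
  writeLines("sentence_id\te1\te2\tlabel\tfiltered\ttokens", con)
  for (inst in instances) {
    writeLines(paste(inst$sentence_id, inst$e1, inst$e2, inst$label,
                     inst$filtered, paste(inst$tokens, collapse = " "),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read instances from the internal line-delimited format
#'
#' @param path path written by [write_instances()].
#' @return List of `mccnn_instance` objects; the label vocabulary is attached
#'   as attribute `"labels"`. A label outside the file's declared vocabulary
#'   is a validation error.
#' @export
read_instances <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L || !startsWith(lines[1], "#labels\t")) {
    stop_validation("'%s' is not an instance file (missing #labels header)", path)
  }
  labels <- strsplit(sub("^#labels\t", "", lines[1]), ",", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L) {
      stop_validation("'%s' line %d: expected 6 tab-separated fields", path, i + 2L)
    }
    if (!(f[4] %in% labels)) {
      stop_validation("'%s' line %d: unknown label '%s'", path, i + 2L, f[4])
    }
    out[[i]] <- new_instance(f[1], f[2], f[3],
                             strsplit(f[6], " ", fixed = TRUE)[[1]], f[4], f[5])
  }
  attr(out, "labels") <- labels
  out
}
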