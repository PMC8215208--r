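#' Disease taxonomies and the multi-level label algebra
#'
#' A `disease_taxonomy` is a rooted tree of disease classes ("Pie"
#' structure): one level-0 root per imaging modality, coarse disease groups
#' at level 1 and finer subclasses at level 2 (deeper levels may be stored
#' but are ignored by the classifier builders). The taxonomy is the single
#' source of truth for class ordering: every score vector, label vector and
#' confusion matrix in the package is ordered by `class_order(tax, level)`.
#'
#' @name taxonomy
NULL

new_taxonomy <- function(modality, nodes, class_order) {
  structure(
    list(modality = modality, nodes = nodes, class_order = class_order,
         max_level = max(vapply(nodes, function(n) n$level, integer(1)))),
    class = "disease_taxonomy")
}

validate_taxonomy <- function(tax) {
  nodes <- tax$nodes
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) {
    stopf("taxonomy structural error: duplicate node id '%s'",
          ids[duplicated(ids)][1])
  }
  levels <- vapply(nodes, function(n) n$level, integer(1))
  if (sum(levels == 0L) != 1L) {
    stopf("taxonomy structural error: need exactly one level-0 root, found %d",
          sum(levels == 0L))
  }
  for (n in nodes) {
    if (n$level == 0L) {
      if (!is.null(n$parent)) {
        stopf("taxonomy structural error: root '%s' must not have a parent", n$id)
      }
      next
    }
    if (is.null(n$parent)) {
      stopf("taxonomy structural error: node '%s' has no parent", n$id)
    }
    p <- match(n$parent, ids)
    if (is.na(p)) {
      stopf("taxonomy structural error: node '%s' cites nonexistent parent '%s'",
            n$id, n$parent)
    }
    if (levels[p] != n$level - 1L) {
      stopf("taxonomy structural error: node '%s' (level %d) has parent '%s' at level %d (must be %d)",
            n$id, n$level, n$parent, levels[p], n$level - 1L)
    }
  }
  for (l in seq_len(tax$max_level)) {
    at_l <- sort(ids[levels == l])
    ord <- tax$class_order[[as.character(l)]]
    if (is.null(ord) || !identical(sort(ord), at_l)) {
      stopf("taxonomy structural error: class_order[%d] is not a permutation of the level-%d node ids", l, l)
    }
  }
  if (!tax$modality %in% c("anterior", "retinal")) {
    stopf("taxonomy structural error: modality must be 'anterior' or 'retinal', got '%s'",
          tax$modality)
  }
  tax
}

#' Load a disease taxonomy from its JSON serialization
#'
#' The file holds a flat node list (`id`, `name`, `level`, `parent`) plus an
#' explicit `class_order` per level, so the ordering survives round trips
#' bit-exactly. Structural violations (duplicate ids, missing parents,
#' parent level not exactly one less than the child's) are errors, never
#' warnings.
#'
#' @param path Path to a taxonomy JSON file.
#' @return A validated `disease_taxonomy` object.
#' @seealso [taxonomy_fixture()] for the taxonomies shipped with the package.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("taxonomy file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- lapply(raw$nodes, function(n) {
    list(id = as.character(n$id), name = as.character(n$name),
         level = as.integer(n$level),
         parent = if (is.null(n$parent)) NULL else as.character(n$parent))
  })
  class_order <- lapply(raw$class_order, function(x)
    vapply(x, as.character, character(1)))
  validate_taxonomy(new_taxonomy(raw$modality, nodes, class_order))
}

#' Save a disease taxonomy to JSON
#'
#' @param tax A `disease_taxonomy`.
#' @param path Output file path.
#' @export
save_taxonomy <- function(tax, path) {
  out <- list(
    modality = tax$modality,
    nodes = lapply(tax$nodes, function(n)
      list(id = n$id, name = n$name, level = n$level,
           parent = if (is.null(n$parent)) NULL else n$parent)),
    class_order = tax$class_order)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Shipped taxonomy fixtures
#'
#' Three editable JSON taxonomies ship with the package: `"anterior"`
#' (4 level-1 disease groups, 9 level-2 subclasses of the anterior
#' segment), `"retinal"` (3 level-1 groups, 8 level-2 subclasses of the
#' fundus) and `"demo"`, a small 2 x 4 hierarchy used by the synthetic
#' end-to-end examples. The level-2 to level-1 parent assignments are a
#' documented clinical-plausibility assumption and can be edited in the
#' JSON files under `inst/extdata`.
#'
#' @param name One of `"anterior"`, `"retinal"`, `"demo"`.
#' @return A validated `disease_taxonomy`.
#' @export
taxonomy_fixture <- function(name = c("anterior", "retinal", "demo")) {
  name <- match.arg(name)
  load_taxonomy(system.file("extdata", paste0("taxonomy_", name, ".json"),
                            package = "hicnet", mustWork = TRUE))
}

node_lookup <- function(tax, id) {
  ids <- vapply(tax$nodes, function(n) n$id, character(1))
  i <- match(id, ids)
  if (is.na(i)) stopf("unknown taxonomy node id '%s'", id)
  tax$nodes[[i]]
}

#' Canonical class order at a taxonomy level
#'
#' @param tax A `disease_taxonomy`.
#' @param level Level (1-based; level 0 is the root).
#' @return Character vector of node ids in canonical order.
#' @export
class_order <- function(tax, level) {
  ord <- tax$class_order[[as.character(level)]]
  if (is.null(ord)) stopf("taxonomy has no level %s", level)
  ord
}

#' Ancestor chain of a taxonomy node
#'
#' Walks parent links from level 1 down to the node's own parent. Level-1
#' nodes and the root return an empty chain.
#'
#' @param tax A `disease_taxonomy`.
#' @param node_id Node id.
#' @return Character vector of ancestor ids ordered from level 1 to the
#'   node's parent level.
#' @export
ancestors <- function(tax, node_id) {
  n <- node_lookup(tax, node_id)
  chain <- character(0)
  while (!is.null(n$parent)) {
    p <- node_lookup(tax, n$parent)
    if (p$level >= 1L) chain <- c(p$id, chain)
    n <- p
  }
  chain
}

#' Expand finest-level labels into a hierarchy-consistent multi-level label
#'
#' Given the set of level-2 subclasses annotated on one image, sets those
#' level-2 bits and the bits of all their level-1 ancestors (upward
#' closure), producing one multi-hot vector per level ordered by
#' [class_order()].
#'
#' @param tax A `disease_taxonomy`.
#' @param finest_labels Character vector of level-2 node ids (non-empty).
#' @return A `multi_level_label`: list with element `levels`, a list of
#'   named 0/1 integer vectors indexed by level.
#' @export
expand_labels <- function(tax, finest_labels) {
  finest_labels <- unique(as.character(finest_labels))
  if (length(finest_labels) == 0) {
    stopf("labeling error: at least one finest-level label is required")
  }
  finest <- 2L
  for (id in finest_labels) {
    n <- node_lookup(tax, id)
    if (n$level != finest) {
      stopf("labeling error: '%s' is a level-%d node, expected level %d",
            id, n$level, finest)
    }
  }
  levels <- list()
  for (l in seq_len(finest)) {
    ord <- class_order(tax, l)
    bits <- stats::setNames(integer(length(ord)), ord)
    levels[[l]] <- bits
  }
  levels[[finest]][finest_labels] <- 1L
  for (id in finest_labels) {
    for (anc in ancestors(tax, id)) {
      lv <- node_lookup(tax, anc)$level
      levels[[lv]][anc] <- 1L
    }
  }
  structure(list(levels = levels), class = "multi_level_label")
}

#' Report hierarchy violations in per-level prediction scores
#'
#' The model does not hard-enforce taxonomy consistency at inference time;
#' this check reports every finer-level class called positive (score
#' strictly above `threshold`) whose level-1 ancestor is not.
#'
#' @param tax A `disease_taxonomy`.
#' @param scores List of per-level numeric score vectors (probabilities in
#'   `[0,1]`), each ordered and sized by [class_order()]; indexed by level.
#' @param threshold Positive-call threshold in (0,1).
#' @return A data frame with one row per violation: `node_id`, `level`,
#'   `score`, `parent_id`, `parent_score`. Zero rows when consistent.
#' @export
check_consistency <- function(tax, scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  for (l in seq_along(scores)) {
    ord <- class_order(tax, l)
    if (length(scores[[l]]) != length(ord)) {
      stopf("shape error: level-%d scores have length %d, expected %d",
            l, length(scores[[l]]), length(ord))
    }
    names(scores[[l]]) <- ord
  }
  out <- data.frame(node_id = character(0), level = integer(0),
                    score = numeric(0), parent_id = character(0),
                    parent_score = numeric(0), stringsAsFactors = FALSE)
  for (l in seq_along(scores)) {
    if (l == 1L) next
    for (id in class_order(tax, l)) {
      s <- scores[[l]][[id]]
      if (s <= threshold) next
      parent <- node_lookup(tax, id)$parent
      ps <- scores[[l - 1L]][[parent]]
      if (ps <= threshold) {
        out <- rbind(out, data.frame(node_id = id, level = l, score = s,
                                     parent_id = parent, parent_score = ps,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Stable content hash of a taxonomy (modality + node list + class order);
# stored in model checkpoints so a model cannot be applied against a
# mismatched class ordering.
taxonomy_hash <- function(tax) {
  payload <- jsonlite::toJSON(list(
    modality = tax$modality,
    nodes = lapply(tax$nodes, function(n) n[c("id", "level", "parent")]),
    class_order = tax$class_order), auto_unbox = TRUE)
  # small FNV-1a over the serialized bytes; stability matters, crypto does not
  bytes <- as.integer(charToRaw(as.character(payload)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.disease_taxonomy <- function(x, ...) {
  cat(sprintf("<disease_taxonomy> modality=%s, max_level=%d\n",
              x$modality, x$max_level))
  for (l in seq_len(min(x$max_level, 2L))) {
    cat(sprintf("  level %d (%d classes): %s\n", l,
                length(class_order(x, l)),
                paste(class_order(x, l), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.multi_level_label <- function(x, ...) {
  for (l in seq_along(x$levels)) {
    pos <- names(x$levels[[l]])[x$levels[[l]] == 1L]
    cat(sprintf("  level %d: %s\n", l,
                if (length(pos)) paste(pos, collapse = ", ") else "-"))
  }
  invisible(x)
}

# Stack multi_level_labels for a manifest into per-level 0/1 matrices
# (rows = samples, columns = class_order).
label_matrices <- function(tax, label_list) {
  lapply(seq_len(2L), function(l) {
    m <- do.call(rbind, lapply(label_list, function(x) x$levels[[l]]))
    rownames(m) <- NULL
    m
  })
}
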