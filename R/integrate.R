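# Repository integration: filter part-record datasets, detect synonyms
# (identical sequence and role) and derivatives (near-identical sequence),
# and merge everything into one network with Synonym nodes and
# identity-weighted similarTo edges.

#' Construct a part-record table
#'
#' A part record is one repository entry: a key (absolute URI), a role
#' drawn from the genetic part types, a display name, an optional
#' description, an optional DNA sequence, and a source label.
#'
#' @param key,role,name Character vectors (recycled to common length).
#' @param description,sequence,source Optional character vectors.
#' @return A `part_records` data frame.
#' @export
part_records <- function(key, role, name, description = "", sequence = "",
                         source = "local") {
  df <- data.frame(key = key, role = role, name = name,
                   description = description, sequence = toupper(sequence),
                   source = source, stringsAsFactors = FALSE)
  class(df) <- c("part_records", "data.frame")
  df
}

#' Filter raw part records into a dataset
#'
#' Filters are applied in a fixed order: `drop_duplicates` first removes
#' every later record whose (sequence, role) pair exactly equals an
#' earlier record from the same source, then `require_description` removes
#' records with empty descriptions. Every removal is explained.
#'
#' @param records A [part_records()] data frame.
#' @param filters Character subset of
#'   `c("drop_duplicates", "require_description")`.
#' @return List with `dataset` (surviving records) and `removed`
#'   (data frame: `key`, `reason`).
#' @export
build_dataset <- function(records, filters = character()) {
  stopifnot(all(filters %in% c("drop_duplicates", "require_description")))
  removed <- data.frame(key = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- records
  if ("drop_duplicates" %in% filters && nrow(keep)) {
    sig <- paste(keep$source, keep$role, keep$sequence, sep = "\r")
    dup <- duplicated(sig) & nzchar(keep$sequence)
    removed <- rbind(removed,
                     data.frame(key = keep$key[dup],
                                reason = rep("duplicate", sum(dup)),
                                stringsAsFactors = FALSE))
    keep <- keep[!dup, , drop = FALSE]
  }
  if ("require_description" %in% filters && nrow(keep)) {
    nodesc <- !nzchar(keep$description)
    removed <- rbind(removed,
                     data.frame(key = keep$key[nodesc],
                                reason = rep("no_description", sum(nodesc)),
                                stringsAsFactors = FALSE))
    keep <- keep[!nodesc, , drop = FALSE]
  }
  rownames(keep) <- NULL
  list(dataset = keep, removed = removed)
}

#' Global-alignment sequence identity
#'
#' Identity between two sequences as the number of matching positions
#' divided by the global alignment length (Needleman-Wunsch with match 1,
#' mismatch -1, gap -1). Symmetric; equals 1 iff the sequences are equal.
#'
#' @param a,b Nonempty sequence strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alen
}

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, 1:(n - k + 1), k:n))
}

.kmer_jaccard <- function(a, b, k) {
  ka <- .kmer_set(a, k); kb <- .kmer_set(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Merge part datasets into one network
#'
#' Records with identical sequence and role (within or across datasets)
#' are synonyms: one record of the group contributes a part node to the
#' network, and each further key becomes a `Synonym` node linked to the
#' survivor by a `synonymOf` edge. Pairs of surviving records with the
#' same role whose alignment identity lies in `[threshold, 1)` get a
#' `similarTo` edge weighted by the identity (derivative candidates). An
#' optional interaction edge list is attached between surviving part
#' nodes (keys of merged-away records are remapped to their survivor).
#' The merged network may comprise several disconnected components.
#'
#' All-pairs comparison is prescreened: candidate pairs must have a
#' sequence length ratio of at least 0.8 and a k-mer Jaccard similarity
#' of at least `min_jaccard` before an alignment is computed. Records
#' without sequences participate by key only and never form synonyms or
#' derivatives.
#'
#' @param datasets List of [part_records()] data frames (one per source).
#' @param threshold Derivative identity threshold in (0, 1).
#' @param interactions Optional data frame with columns
#'   `subject`, `predicate`, `object` (collapsed regulatory predicates).
#' @param filters Filters applied per dataset via [build_dataset()].
#' @param kmer_k,min_jaccard Prescreen parameters.
#' @param use_prescreen Disable to force alignment of every same-role pair.
#' @return List with `graph` (a `design_graph`) and `report`
#'   (a `merge_report`: `synonyms`, `derivatives`, `removed`).
#' @export
merge_datasets <- function(datasets, threshold = 0.95, interactions = NULL,
                           filters = character(),
                           kmer_k = cg_config()[["kmer.k"]],
                           min_jaccard = cg_config()[["kmer.min_jaccard"]],
                           use_prescreen = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0,1)")
  }
  if (inherits(datasets, "data.frame")) datasets <- list(datasets)
  removed <- data.frame(key = character(), reason = character(),
                        stringsAsFactors = FALSE)
  recs <- list()
  for (ds in datasets) {
    bd <- build_dataset(ds, filters)
    removed <- rbind(removed, bd$removed)
    recs[[length(recs) + 1L]] <- bd$dataset
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs)) {
    return(list(graph = design_graph(),
                report = .merge_report(removed = removed)))
  }
  recs$key <- normalize_uri(recs$key)
  recs <- recs[!duplicated(recs$key), , drop = FALSE]
  rownames(recs) <- NULL

  # synonym groups: identical (sequence, role), sequences required
  sig <- ifelse(nzchar(recs$sequence),
                paste(recs$role, recs$sequence, sep = "\r"), NA)
  survivor_of <- stats::setNames(recs$key, recs$key)
  synonyms <- data.frame(a = character(), b = character(),
                         basis = character(), stringsAsFactors = FALSE)
  first_of_sig <- !duplicated(sig) | is.na(sig)
  for (i in which(!first_of_sig)) {
    j <- match(sig[i], sig)
    survivor_of[recs$key[i]] <- recs$key[j]
    synonyms <- rbind(synonyms, data.frame(
      a = recs$key[j], b = recs$key[i], basis = "sequence+role",
      stringsAsFactors = FALSE))
  }
  surv <- recs[first_of_sig, , drop = FALSE]

  # derivative detection among survivors with sequences, same role
  derivatives <- data.frame(a = character(), b = character(),
                            identity = numeric(), stringsAsFactors = FALSE)
  withseq <- which(nzchar(surv$sequence))
  if (length(withseq) > 1) {
    idx <- utils::combn(withseq, 2)
    for (c2 in seq_len(ncol(idx))) {
      i <- idx[1, c2]; j <- idx[2, c2]
      if (surv$role[i] != surv$role[j]) next
      la <- nchar(surv$sequence[i]); lb <- nchar(surv$sequence[j])
      if (min(la, lb) / max(la, lb) < 0.8) next
      if (use_prescreen &&
          .kmer_jaccard(surv$sequence[i], surv$sequence[j],
                        kmer_k) < min_jaccard) next
      idy <- pairwise_identity(surv$sequence[i], surv$sequence[j])
      if (idy >= threshold && idy < 1) {
        derivatives <- rbind(derivatives, data.frame(
          a = min(surv$key[i], surv$key[j]),
          b = max(surv$key[i], surv$key[j]),
          identity = idy, stringsAsFactors = FALSE))
      }
    }
  }

  g <- design_graph()
  for (i in seq_len(nrow(surv))) {
    props <- c(name = surv$name[i], source = surv$source[i])
    if (nzchar(surv$description[i])) props["description"] <- surv$description[i]
    if (nzchar(surv$sequence[i])) props["sequence"] <- surv$sequence[i]
    g <- graph_add_node(g, surv$key[i], surv$role[i], props)
  }
  for (i in seq_len(nrow(synonyms))) {
    rec <- recs[recs$key == synonyms$b[i], , drop = FALSE]
    g <- graph_add_node(g, synonyms$b[i], "Synonym",
                        c(name = rec$name[1], source = rec$source[1]))
    g <- graph_add_edge(g, synonyms$a[i], "synonymOf", synonyms$b[i])
  }
  for (i in seq_len(nrow(derivatives))) {
    g <- graph_add_edge(g, derivatives$a[i], "similarTo", derivatives$b[i],
                        weight = derivatives$identity[i])
  }
  if (!is.null(interactions) && nrow(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      s <- survivor_of[normalize_uri(interactions$subject[i])]
      o <- survivor_of[normalize_uri(interactions$object[i])]
      if (is.na(s) || is.na(o)) {
        cg_log("warn", "integrate", sprintf(
          "interaction %s -> %s references unknown records; skipped",
          interactions$subject[i], interactions$object[i]))
        next
      }
      g <- graph_add_edge(g, s, interactions$predicate[i], o)
    }
  }
  list(graph = g,
       report = .merge_report(synonyms = synonyms,
                              derivatives = derivatives, removed = removed))
}

.merge_report <- function(synonyms = NULL, derivatives = NULL,
                          removed = NULL) {
  if (is.null(synonyms)) {
    synonyms <- data.frame(a = character(), b = character(),
                           basis = character(), stringsAsFactors = FALSE)
  }
  if (is.null(derivatives)) {
    derivatives <- data.frame(a = character(), b = character(),
                              identity = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(removed)) {
    removed <- data.frame(key = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  structure(list(synonyms = synonyms, derivatives = derivatives,
                 removed = removed), class = "merge_report")
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(
    "<merge_report> %d synonym pair(s), %d derivative edge(s), %d record(s) removed\n",
    nrow(x$synonyms), nrow(x$derivatives), nrow(x$removed)))
  invisible(x)
}
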