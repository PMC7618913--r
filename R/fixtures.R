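# Deterministic generators for synthetic designs and part corpora with
# planted structure. Every generator is a pure function of its spec and
# seed (the session RNG state is saved and restored), so identical inputs
# give byte-identical outputs. Sequences are uniform random DNA with no
# codon structure; the generators emulate design-shaped structure, not
# biology.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.fixture_ns <- "https://fixtures.circuitgraph.local"

# one transcription unit: promoter + RBS + CDS + terminator under a unit
# region, a protein, a genetic-production interaction (CDS -> protein) and
# a repression interaction (repressor protein onto the promoter)
.add_unit <- function(g, base, unit, repressor_key = NULL, seed_lengths) {
  u <- sprintf("%s/unit_%s", base, unit)
  parts <- c(promoter = sprintf("%s/p%s", u, unit),
             rbs = sprintf("%s/rbs_%s", u, unit),
             cds = sprintf("%s/cds_%s", u, unit),
             terminator = sprintf("%s/t%s", u, unit))
  prot <- sprintf("%s/protein_%s", base, unit)
  g <- graph_add_node(g, u, "Engineered-Region",
                      c(name = sprintf("unit_%s", unit)))
  g <- graph_add_node(g, parts["promoter"], "Promoter",
                      c(name = sprintf("p%s", unit),
                        sequence = .random_dna(seed_lengths["promoter"])))
  g <- graph_add_node(g, parts["rbs"], "RBS",
                      c(name = sprintf("rbs_%s", unit),
                        sequence = .random_dna(seed_lengths["rbs"])))
  g <- graph_add_node(g, parts["cds"], "CDS",
                      c(name = sprintf("cds_%s", unit),
                        sequence = .random_dna(seed_lengths["cds"])))
  g <- graph_add_node(g, parts["terminator"], "Terminator",
                      c(name = sprintf("t%s", unit),
                        sequence = .random_dna(seed_lengths["terminator"])))
  g <- graph_add_node(g, prot, "Protein",
                      c(name = sprintf("protein_%s", unit)))
  for (p in parts) g <- graph_add_edge(g, u, "hasPart", p)

  prod <- sprintf("%s/production_%s", base, unit)
  g <- graph_add_node(g, prod, "Interaction")
  g <- graph_add_node(g, .sbo_interaction_terms[["genetic_production"]],
                      "Metadata", c(name = "genetic production"))
  g <- graph_add_edge(g, prod, "interactionType",
                      .sbo_interaction_terms[["genetic_production"]])
  g <- graph_add_edge(g, prod, "hasParticipant", parts["cds"],
                      role = "template")
  g <- graph_add_edge(g, prod, "hasParticipant", prot, role = "product")
  list(graph = g, unit = u, parts = parts, protein = prot)
}

.add_repression <- function(g, base, label, repressor, promoter) {
  rint <- sprintf("%s/repression_%s", base, label)
  g <- graph_add_node(g, rint, "Interaction")
  g <- graph_add_node(g, .sbo_interaction_terms[["repression"]], "Metadata",
                      c(name = "repression"))
  g <- graph_add_edge(g, rint, "interactionType",
                      .sbo_interaction_terms[["repression"]])
  g <- graph_add_edge(g, rint, "hasParticipant", repressor,
                      role = "inhibitor")
  g <- graph_add_edge(g, rint, "hasParticipant", promoter,
                      role = "inhibited")
  g
}

.part_lengths <- c(promoter = 50L, rbs = 20L, cds = 120L, terminator = 40L)

#' Generate a synthetic design with known structure
#'
#' Kinds:
#' \describe{
#'   \item{not_gate}{one root carrying a promoter + RBS + CDS + terminator
#'     unit, one protein, one genetic-production interaction and one
#'     repression interaction of the protein onto the promoter.}
#'   \item{repressilator}{three such units whose proteins repress the next
#'     unit's promoter in a 3-cycle.}
#'   \item{nested_design}{a containment tree of engineered regions of the
#'     given `depth` and `breadth`, with coding sequences as leaves.}
#'   \item{genbank_flat}{a GenBank flat file with promoter, CDS and
#'     terminator features over a random sequence.}
#' }
#'
#' @param kind Design kind.
#' @param seed Integer seed; identical kind + seed + params give
#'   byte-identical documents.
#' @param params Named list (`depth`, `breadth` for `nested_design`).
#' @return List with `graph` (a `design_graph`; `NULL` for
#'   `genbank_flat`), `doc` (serialized SBOL3 document, or the GenBank
#'   text), and `manifest` (expected structure: node/edge counts per view
#'   and planted relations).
#' @export
make_design <- function(kind = c("not_gate", "repressilator",
                                 "nested_design", "genbank_flat"),
                        seed = 1L, params = list()) {
  if (!is.character(kind) || !kind[1] %in% c("not_gate", "repressilator",
                                             "nested_design",
                                             "genbank_flat")) {
    stop(sprintf("invalid design kind '%s'", kind[1]))
  }
  kind <- match.arg(kind)
  .with_seed(seed, {
    base <- sprintf("%s/%s_%d", .fixture_ns, kind, seed)
    if (kind == "not_gate") {
      g <- design_graph()
      g <- graph_add_node(g, base, "Engineered-Region", c(name = "not_gate"))
      g <- graph_set_root(g, base)
      u <- .add_unit(g, base, "a", seed_lengths = .part_lengths)
      g <- u$graph
      g <- graph_add_edge(g, base, "hasPart", u$unit)
      g <- .add_repression(g, base, "a", u$protein, u$parts[["promoter"]])
      manifest <- list(
        roots = 1L, interactions = 2L,
        interaction_view_edges = 2L,
        interaction_view_predicates = c(produces = 1L, represses = 1L),
        repressor = u$protein, repressed_promoter = u$parts[["promoter"]],
        hierarchy_nodes = 6L, hierarchy_edges = 5L)
      list(kind = kind, seed = seed, graph = g, doc = write_sbol(g),
           manifest = manifest)
    } else if (kind == "repressilator") {
      g <- design_graph()
      g <- graph_add_node(g, base, "Engineered-Region",
                          c(name = "repressilator"))
      g <- graph_set_root(g, base)
      units <- list()
      for (i in 1:3) {
        u <- .add_unit(g, base, letters[i], seed_lengths = .part_lengths)
        g <- u$graph
        g <- graph_add_edge(g, base, "hasPart", u$unit)
        units[[i]] <- u
      }
      for (i in 1:3) {
        j <- i %% 3 + 1
        g <- .add_repression(g, base, letters[i], units[[i]]$protein,
                             units[[j]]$parts[["promoter"]])
      }
      manifest <- list(
        roots = 1L, interactions = 6L,
        interaction_view_edges = 6L,
        interaction_view_predicates = c(produces = 3L, represses = 3L),
        protein_cycle = vapply(units, `[[`, "", "protein"),
        hierarchy_nodes = 16L, hierarchy_edges = 15L)
      list(kind = kind, seed = seed, graph = g, doc = write_sbol(g),
           manifest = manifest)
    } else if (kind == "nested_design") {
      depth <- params$depth %||% 2L
      breadth <- params$breadth %||% 2L
      g <- design_graph()
      g <- graph_add_node(g, base, "Engineered-Region", c(name = "nested"))
      g <- graph_set_root(g, base)
      n_nodes <- 1L; n_edges <- 0L
      frontier <- base
      for (d in seq_len(depth)) {
        nxt <- character()
        for (parent in frontier) {
          for (b in seq_len(breadth)) {
            child <- sprintf("%s/c%d", parent, b)
            if (d == depth) {
              g <- graph_add_node(g, child, "CDS",
                                  c(sequence = .random_dna(60L)))
            } else {
              g <- graph_add_node(g, child, "Engineered-Region")
            }
            g <- graph_add_edge(g, parent, "hasPart", child)
            n_nodes <- n_nodes + 1L; n_edges <- n_edges + 1L
            nxt <- c(nxt, child)
          }
        }
        frontier <- nxt
      }
      manifest <- list(roots = 1L, hierarchy_nodes = n_nodes,
                       hierarchy_edges = n_edges, depth = depth,
                       breadth = breadth)
      list(kind = kind, seed = seed, graph = g, doc = write_sbol(g),
           manifest = manifest)
    } else {
      seq_len_total <- 400L
      fullseq <- .random_dna(seq_len_total)
      feats <- list(
        list(key = "promoter", label = "pfix", start = 10L, end = 59L,
             reverse = FALSE),
        list(key = "CDS", label = "gfp", start = 80L, end = 259L,
             reverse = FALSE),
        list(key = "terminator", label = "tfix", start = 280L, end = 319L,
             reverse = TRUE))
      locus <- sprintf("FIX%04d", seed %% 10000)
      lines <- c(sprintf(
        "LOCUS       %s              %d bp    DNA     linear   SYN 01-JAN-2024",
        locus, seq_len_total),
        "DEFINITION  synthetic fixture record.",
        "FEATURES             Location/Qualifiers",
        sprintf("     source          1..%d", seq_len_total))
      for (f in feats) {
        loc <- sprintf("%d..%d", f$start + 1L, f$end)
        if (f$reverse) loc <- sprintf("complement(%s)", loc)
        lines <- c(lines,
                   sprintf("     %-15s %s", f$key, loc),
                   sprintf("                     /label=\"%s\"", f$label))
      }
      lines <- c(lines, "ORIGIN")
      for (off in seq(1L, seq_len_total, by = 60L)) {
        chunk <- substr(fullseq, off, min(off + 59L, seq_len_total))
        groups <- substring(chunk, seq(1, nchar(chunk), 10),
                            pmin(seq(10, nchar(chunk) + 9, 10),
                                 nchar(chunk)))
        lines <- c(lines, sprintf("%9d %s", off,
                                  tolower(paste(groups, collapse = " "))))
      }
      lines <- c(lines, "//", "")
      manifest <- list(mapped_features = 3L,
                       feature_types = c(Promoter = 1L, CDS = 1L,
                                         Terminator = 1L),
                       locus = locus, reverse_features = 1L)
      list(kind = kind, seed = seed, graph = NULL,
           doc = paste(lines, collapse = "\n"), manifest = manifest)
    }
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate a part corpus with planted synonyms and derivatives
#'
#' Generates `n_records` random part records (seeded), then plants exact
#' duplicates (`dup_rate` fraction of records duplicated under new keys
#' with new names: planted synonyms) and mutated copies (`mutation_rate`
#' fraction duplicated with point substitutions at `per_base_rate` per
#' eligible position: planted derivatives). Mutations never touch the
#' first or last five bases (so the planted length ratio stays 1) and are
#' kept at least eight bases apart, so the ungapped alignment is the
#' unique optimum and the planted identity `1 - k/L` is exact. The
#' manifest records every planted pair and its exact sequence identity.
#'
#' @param seed Integer seed.
#' @param n_records Number of base records.
#' @param dup_rate Fraction of base records duplicated exactly.
#' @param mutation_rate Fraction of base records duplicated with mutations.
#' @param per_base_rate Substitution probability per eligible base.
#' @param source Source label for the corpus.
#' @return List with `records` (a [part_records()] data frame) and
#'   `manifest` (data frame: `a`, `b`, `kind`, `identity`).
#' @export
make_part_corpus <- function(seed = 1L, n_records = 20L, dup_rate = 0.1,
                             mutation_rate = 0, per_base_rate = 0.03,
                             source = "fixture_corpus") {
  .with_seed(seed, {
    roles <- c("Promoter", "RBS", "CDS", "Terminator")
    base_ns <- sprintf("%s/corpus_%d", .fixture_ns, seed)
    lens <- sample(60:200, n_records, replace = TRUE)
    role <- sample(roles, n_records, replace = TRUE)
    seqs <- vapply(lens, .random_dna, "")
    key <- sprintf("%s/%s_part_%03d/1", base_ns, source, seq_len(n_records))
    recs <- part_records(
      key = key, role = role,
      name = sprintf("%s_part_%03d", source, seq_len(n_records)),
      description = sprintf("synthetic %s fixture record %d",
                            tolower(role), seq_len(n_records)),
      sequence = seqs, source = source)
    manifest <- data.frame(a = character(), b = character(),
                           kind = character(), identity = numeric(),
                           stringsAsFactors = FALSE)
    n_dup <- floor(dup_rate * n_records)
    n_mut <- floor(mutation_rate * n_records)
    pool <- sample(n_records, n_dup + n_mut)
    dup_idx <- pool[seq_len(n_dup)]
    mut_idx <- pool[n_dup + seq_len(n_mut)]
    for (i in dup_idx) {
      nk <- sprintf("%s/%s_dup_%03d/1", base_ns, source, i)
      recs <- rbind(recs, part_records(
        key = nk, role = role[i],
        name = sprintf("%s_dup_%03d", source, i),
        description = sprintf("duplicate of record %d", i),
        sequence = seqs[i], source = source))
      manifest <- rbind(manifest, data.frame(
        a = key[i], b = nk, kind = "synonym", identity = 1,
        stringsAsFactors = FALSE))
    }
    for (i in mut_idx) {
      s <- strsplit(seqs[i], "")[[1]]
      eligible <- seq_along(s)
      eligible <- eligible[eligible > 5 & eligible <= length(s) - 5]
      hit <- eligible[stats::runif(length(eligible)) < per_base_rate]
      # keep substitutions isolated (>= 8 bases apart): the ungapped
      # diagonal then stays the unique optimal global alignment, so the
      # planted identity 1 - k/L is the exact alignment identity
      if (length(hit) > 1) {
        kept <- hit[1]
        for (h in hit[-1]) if (h - kept[length(kept)] >= 8) kept <- c(kept, h)
        hit <- kept
      }
      for (pos in hit) {
        s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
      }
      mseq <- paste(s, collapse = "")
      idy <- 1 - length(hit) / length(s)
      nk <- sprintf("%s/%s_var_%03d/1", base_ns, source, i)
      recs <- rbind(recs, part_records(
        key = nk, role = role[i],
        name = sprintf("%s_var_%03d", source, i),
        description = sprintf("variant of record %d", i),
        sequence = mseq, source = source))
      manifest <- rbind(manifest, data.frame(
        a = key[i], b = nk,
        kind = if (length(hit)) "derivative" else "synonym",
        identity = idy, stringsAsFactors = FALSE))
    }
    rownames(recs) <- NULL
    list(records = recs, manifest = manifest, seed = seed,
         params = list(n_records = n_records, dup_rate = dup_rate,
                       mutation_rate = mutation_rate,
                       per_base_rate = per_base_rate))
  })
}
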