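# GenBank flat-file reader (LOCUS / FEATURES / ORIGIN subset). Each record
# becomes one root Engineered-Region; mapped features become typed part
# nodes under it. GenBank coordinates (1-based, inclusive) are converted to
# 0-based half-open ranges in node properties; complement-strand features
# get orientation "reverse" with the sequence stored as the forward-strand
# slice (lossless round trip).

.genbank_feature_map <- c(
  "CDS" = "CDS",
  "promoter" = "Promoter",
  "RBS" = "RBS",
  "ribosome_binding_site" = "RBS",
  "terminator" = "Terminator"
)

.genbank_namespace <- "https://genbank.local"

.parse_genbank_location <- function(loc) {
  rev <- grepl("^complement\\(", loc)
  core <- gsub("^complement\\(|\\)$", "", loc)
  core <- gsub("[<>]", "", core)
  m <- regmatches(core, regexec("^(\\d+)\\.\\.(\\d+)$", core))[[1]]
  if (length(m) == 3) {
    start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
  } else if (grepl("^\\d+$", core)) {
    start1 <- end1 <- as.integer(core)
  } else {
    return(NULL)
  }
  list(start0 = start1 - 1L, end0 = end1, reverse = rev)
}

.read_genbank_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  g <- design_graph()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^LOCUS", lines[i])) {
      if (grepl("^\\s*$", lines[i]) || grepl("^//", lines[i])) {
        i <- i + 1L
        next
      }
      stop(sprintf("GenBank parse error at line %d: expected LOCUS header",
                   i))
    }
    locus <- strsplit(trimws(sub("^LOCUS", "", lines[i])), "\\s+")[[1]][1]
    root <- sprintf("%s/%s", .genbank_namespace, locus)
    i <- i + 1L
    feats <- list()
    seq <- character()
    in_features <- FALSE
    cur <- NULL
    while (i <= n && !grepl("^//", lines[i])) {
      ln <- lines[i]
      if (grepl("^FEATURES", ln)) {
        in_features <- TRUE
      } else if (grepl("^ORIGIN", ln)) {
        in_features <- FALSE
        i <- i + 1L
        while (i <= n && !grepl("^//", lines[i])) {
          seq <- c(seq, gsub("[^A-Za-z]", "", lines[i]))
          i <- i + 1L
        }
        break
      } else if (in_features) {
        if (grepl("^ {5}\\S", ln)) {
          if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
          parts <- strsplit(trimws(ln), "\\s+")[[1]]
          if (length(parts) < 2) {
            stop(sprintf("GenBank parse error at line %d: malformed feature",
                         i))
          }
          cur <- list(key = parts[1], location = parts[2],
                      qualifiers = character())
        } else if (grepl("^ {10,}/", ln) && !is.null(cur)) {
          q <- sub("^\\s*/", "", ln)
          kv <- strsplit(q, "=", fixed = TRUE)[[1]]
          if (length(kv) >= 2) {
            val <- gsub("^\"|\"$", "", paste(kv[-1], collapse = "="))
            cur$qualifiers[kv[1]] <- val
          }
        }
      }
      i <- i + 1L
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
    if (i <= n && grepl("^//", lines[i])) i <- i + 1L
    fullseq <- toupper(paste(seq, collapse = ""))

    rootprops <- c(name = locus, locus = locus)
    if (nzchar(fullseq)) rootprops["sequence"] <- fullseq
    g <- graph_add_node(g, root, "Engineered-Region", rootprops)
    g <- graph_set_root(g, root)
    counter <- stats::setNames(integer(0), character(0))
    for (f in feats) {
      if (f$key == "source") next
      nt <- unname(.genbank_feature_map[f$key])
      if (is.na(nt)) {
        cg_log("warn", "io", sprintf(
          "GenBank feature key '%s' has no part-type mapping; kept as Engineered-Region",
          f$key))
        nt <- "Engineered-Region"
      }
      loc <- .parse_genbank_location(f$location)
      if (is.null(loc)) {
        cg_log("warn", "io", sprintf(
          "GenBank feature '%s' at %s: unsupported location; skipped",
          f$key, f$location))
        next
      }
      cnt <- if (is.na(counter[f$key])) 1L else counter[f$key] + 1L
      counter[f$key] <- cnt
      label <- f$qualifiers["label"]
      if (is.na(label)) label <- f$qualifiers["gene"]
      slug <- if (!is.na(label)) gsub("[^A-Za-z0-9_.-]", "_", label) else
        sprintf("%s_%d", f$key, cnt)
      key <- sprintf("%s/%s", root, slug)
      props <- c(name = if (!is.na(label)) unname(label) else slug,
                 start = as.character(loc$start0),
                 end = as.character(loc$end0),
                 orientation = if (loc$reverse) "reverse" else "forward")
      if (nzchar(fullseq) && loc$end0 <= nchar(fullseq)) {
        props["sequence"] <- substr(fullseq, loc$start0 + 1L, loc$end0)
      }
      if (!is.na(f$qualifiers["note"])) {
        props["description"] <- unname(f$qualifiers["note"])
      }
      g <- graph_add_node(g, key, nt, props)
      g <- graph_add_edge(g, root, "hasPart", key)
    }
  }
  g
}
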