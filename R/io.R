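# File formats: PHYLIP / FASTA alignments (through ape), a plain-text
# population-model file, and an event-annotated Newick dialect that
# carries the (time, kind, from, to) label-switch events on branches.

aln_to_DNAbin <- function(aln) ape::as.DNAbin(tolower(aln))

DNAbin_to_aln <- function(x) {
  m <- toupper(as.character(as.matrix(x)))
  tolower(m)
}

#' Write a locus alignment
#'
#' @param aln character matrix (tips x sites) with tip rownames.
#' @param path output file.
#' @param format `"phylip"` (sequential), `"interleaved"`, or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("phylip", "interleaved",
                                                  "fasta")) {
  format <- match.arg(format)
  x <- aln_to_DNAbin(aln)
  if (format == "fasta") {
    ape::write.FASTA(x, path)
  } else {
    ape::write.dna(x, path,
                   format = if (format == "phylip") "sequential"
                            else "interleaved",
                   colsep = "", nbcol = -1, colw = 1e9)
  }
  invisible(path)
}

#' Read multi-locus alignments with population labels
#'
#' Reads one file per locus (PHYLIP sequential or interleaved, or FASTA)
#' and resolves each tip's population. By default tip names of the form
#' `<population>_<k>` are mapped by their prefix against the model's
#' population labels; an explicit `sample_map` (data frame with columns
#' `tip`, `population`) overrides this.
#'
#' @param paths character vector of alignment files, one per locus.
#' @param model a [pop_model()].
#' @param format `"auto"` (sniff FASTA by a leading `>`), `"phylip"`,
#'   `"interleaved"`, or `"fasta"`.
#' @param sample_map optional data frame mapping tip names to population
#'   labels.
#' @return a `coaldiv_data` (without genealogies).
#' @export
read_alignments <- function(paths, model, format = "auto",
                            sample_map = NULL) {
  stopifnot(inherits(model, "pop_model"), length(paths) >= 1)
  als <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("alignment file not found: ", p)
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (startsWith(trimws(readLines(p, n = 1L)), ">")) "fasta"
             else "phylip"
    }
    x <- switch(fmt,
      fasta = ape::read.FASTA(p),
      phylip = ape::read.dna(p, format = "sequential"),
      interleaved = ape::read.dna(p, format = "interleaved"),
      stop("unknown format: ", fmt))
    DNAbin_to_aln(x)
  })
  tips <- rownames(als[[1]])
  if (anyDuplicated(tips)) stop("duplicated tip names: ",
                                paste(tips[duplicated(tips)], collapse = ", "))
  for (l in seq_along(als)) {
    if (!setequal(rownames(als[[l]]), tips)) {
      stop("locus ", l, " has a different tip set than locus 1")
    }
    als[[l]] <- als[[l]][tips, , drop = FALSE]
  }
  if (is.null(sample_map)) {
    pop <- sub("_[^_]*$", "", tips)
  } else {
    pop <- sample_map$population[match(tips, sample_map$tip)]
    if (anyNA(pop)) {
      stop("tips absent from the sample map: ",
           paste(tips[is.na(pop)], collapse = ", "))
    }
  }
  idx <- match(pop, model$labels)
  if (anyNA(idx)) {
    stop("unknown population label for tip(s): ",
         paste(tips[is.na(idx)], collapse = ", "))
  }
  structure(list(model = model, alignments = als, genealogies = NULL,
                 tip_pop = idx, tip_labels = tips,
                 sites = ncol(als[[1]])),
            class = "coaldiv_data")
}

#' Event-annotated Newick serialization
#'
#' Writes an [event_genealogy()] as a Newick string whose branches carry
#' their label-switch events in comment blocks
#' `[&pop=<i>,ev=<kind>:<from>:<to>:<time>;...]`. [read_event_newick()]
#' recovers topology, labels and events exactly and node times to within
#' floating-point reconstruction error of the printed branch lengths.
#'
#' @param g an [event_genealogy()].
#' @param path optional file; when given the string is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_event_newick <- function(g, path = NULL) {
  ch <- children_of(g)
  fmt_ev <- function(v) {
    e <- g$events[g$events$node == v, , drop = FALSE]
    e <- e[order(e$time), , drop = FALSE]
    tag <- sprintf("pop=%d", g$node_pop[v])
    if (nrow(e)) {
      tag <- paste0(tag, ",ev=", paste(
        sprintf("%s:%d:%d:%.17g", e$kind, e$from, e$to, e$time),
        collapse = ";"))
    }
    paste0("[&", tag, "]")
  }
  rec <- function(v) {
    body <- if (v <= g$n_tips) g$tip_labels[v] else {
      paste0("(", rec(ch[[v]][1]), ",", rec(ch[[v]][2]), ")")
    }
    p <- g$parent[v]
    if (p == 0L) return(paste0(body, fmt_ev(v), ";"))
    paste0(body, fmt_ev(v), ":",
           sprintf("%.17g", g$node_time[p] - g$node_time[v]))
  }
  s <- rec(root_node(g))
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname write_event_newick
#' @param x an event-annotated Newick string or a file containing one.
#' @param locus locus id to store on the genealogy.
#' @export
read_event_newick <- function(x, locus = 1L) {
  if (length(x) == 1 && !grepl("\\(", x) && file.exists(x)) {
    x <- paste(readLines(x), collapse = "")
  }
  s <- gsub("\\s", "", paste(x, collapse = ""))
  pos <- 1L
  peek <- function() substr(s, pos, pos)
  take_until <- function(stops) {
    from <- pos
    while (pos <= nchar(s) && !substr(s, pos, pos) %in% stops) {
      pos <<- pos + 1L
    }
    substr(s, from, pos - 1L)
  }
  nodes <- list()   # per node: label, kids, comment, blen
  parse_node <- function() {
    kids <- integer(0)
    label <- ""
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- c(kids, parse_node())
      while (peek() == ",") {
        pos <<- pos + 1L
        kids <- c(kids, parse_node())
      }
      stopifnot(peek() == ")")
      pos <<- pos + 1L
    } else {
      label <- take_until(c("[", ":", ",", ")", ";"))
    }
    comment <- ""
    if (peek() == "[") {
      from <- pos
      while (substr(s, pos, pos) != "]") pos <<- pos + 1L
      pos <<- pos + 1L
      comment <- substr(s, from, pos - 1L)
    }
    blen <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      blen <- as.numeric(take_until(c(",", ")", ";")))
    }
    nodes[[length(nodes) + 1L]] <<- list(label = label, kids = kids,
                                         comment = comment, blen = blen)
    length(nodes)
  }
  ridx <- parse_node()
  n_tip <- sum(vapply(nodes, function(x) length(x$kids) == 0, TRUE))
  m <- length(nodes)
  stopifnot(m == 2L * n_tip - 1L)
  # assign node ids: tips 1..n in parse order, internals n+1..
  ids <- integer(m)
  tid <- 0L; iid <- n_tip
  for (i in seq_len(m)) {
    if (length(nodes[[i]]$kids) == 0) { tid <- tid + 1L; ids[i] <- tid }
    else { iid <- iid + 1L; ids[i] <- iid }
  }
  parent <- integer(m); node_time <- numeric(m); node_pop <- integer(m)
  tip_labels <- character(n_tip)
  evs <- empty_events()
  # depths from root, then convert to times (tips at 0)
  depth <- numeric(m)
  walk <- function(i, d) {
    depth[ids[i]] <<- d
    for (k in nodes[[i]]$kids) {
      parent[ids[k]] <<- ids[i]
      walk(k, d + nodes[[k]]$blen)
    }
  }
  walk(ridx, 0)
  h <- max(depth)
  for (i in seq_len(m)) {
    v <- ids[i]
    node_time[v] <- h - depth[v]
    if (length(nodes[[i]]$kids) == 0) tip_labels[v] <- nodes[[i]]$label
    cm <- nodes[[i]]$comment
    pm <- regmatches(cm, regexec("pop=([0-9]+)", cm))[[1]]
    node_pop[v] <- as.integer(pm[2])
    em <- regmatches(cm, regexec("ev=([^]]+)", cm))[[1]]
    if (length(em)) {
      for (tok in strsplit(em[2], ";", fixed = TRUE)[[1]]) {
        f <- strsplit(tok, ":", fixed = TRUE)[[1]]
        evs <- rbind(evs, data.frame(node = v, time = as.numeric(f[4]),
                                     kind = f[1], from = as.integer(f[2]),
                                     to = as.integer(f[3])))
      }
    }
  }
  node_time[seq_len(n_tip)] <- 0   # clean rounding at the tips
  new_event_genealogy(n_tip, tip_labels[seq_len(n_tip)],
                      node_pop[seq_len(n_tip)], parent, node_time,
                      node_pop, evs[order(evs$node, evs$time), ,
                                    drop = FALSE], locus)
}

#' Parse a population-model file
#'
#' Plain-text `key = value` format with three keys: `populations`
#' (space-separated labels), `samples` (space-separated counts), and
#' `adjacency` (comma-separated rows of the character matrix; see
#' [pop_model()] for the codes, `-` on the diagonal). Lines starting with
#' `#` are comments.
#'
#' @param path model file.
#' @return a [pop_model()].
#' @export
read_model_file <- function(path) {
  kv <- parse_config(path)
  need <- c("populations", "samples")
  if (!all(need %in% names(kv))) {
    stop("model file must define: ", paste(need, collapse = ", "))
  }
  labels <- strsplit(trimws(kv$populations), "\\s+")[[1]]
  counts <- as.integer(strsplit(trimws(kv$samples), "\\s+")[[1]])
  adj <- NULL
  if (!is.null(kv$adjacency)) {
    rows <- strsplit(trimws(strsplit(kv$adjacency, ",")[[1]]), "")
    adj <- do.call(rbind, rows)
  }
  pop_model(labels, counts, adjacency = adj)
}

#' @rdname read_model_file
#' @export
parse_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- list()
  for (l in ln) {
    m <- regexec("^([^=]+)=(.*)$", l)[[1]]
    if (m[1] == -1) stop("cannot parse config line: ", l)
    key <- trimws(substr(l, m[2], m[2] + attr(m, "match.length")[2] - 1))
    val <- trimws(substr(l, m[3], nchar(l)))
    kv[[key]] <- val
  }
  kv
}

#' Write posterior outputs as TSV
#'
#' Writes the retained samples, the per-parameter summary, and per-
#' parameter histograms, each as a TSV whose header comments record the
#' seed and settings so a rerun with the same seed reproduces the files
#' bit-exactly.
#'
#' @param fit a `coaldiv_fit` from [run_chain()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fit_tsv <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# coaldiv %s", as.character(utils::packageVersion("coaldiv"))),
           sprintf("# seed = %d", fit$seed),
           sprintf("# iterations = %d, burnin = %d, thin = %d",
                   fit$chain$iterations, fit$chain$burnin, fit$chain$thin))
  wr <- function(df, f) {
    p <- file.path(dir, f)
    writeLines(hdr, p)
    suppressWarnings(utils::write.table(df, p, append = TRUE, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
  }
  wr(fit$samples, "samples.tsv")
  wr(fit$summary, "summary.tsv")
  hists <- dplyr::bind_rows(lapply(names(fit$samples), function(nm) {
    rng <- prior_support(fit$priors$priors[[nm]])
    br <- seq(rng[1], rng[2], length.out = fit$chain$bins + 1L)
    cnt <- tabulate(findInterval(fit$samples[[nm]], br,
                                 rightmost.closed = TRUE), fit$chain$bins)
    tibble(parameter = nm, bin_mid = (br[-1] + br[-length(br)]) / 2,
           density = cnt / sum(cnt) / diff(br)[1])
  }))
  wr(hists, "histograms.tsv")
  invisible(dir)
}
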