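# Independent oracles used to cross-check the package's own algorithms.
# Each is deliberately implemented with different machinery than the code
# path it validates (base-R regex, utils::adist, exhaustive subset search,
# Biostrings alignments).

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_regex <- function(branch) {
  paste(vapply(strsplit(branch, "")[[1]], function(ch)
    paste0("[", IUPAC_SETS[[ch]], "]"), character(1)), collapse = "")
}

# regex oracle for spacer-site enumeration: overlapping matches via
# zero-width lookahead on each strand, coordinates mapped like the
# contract specifies
oracle_pam_sites <- function(seq, pam, len) {
  L <- nchar(seq)
  one <- function(s) {
    if (pam$pamless) {
      if (L < len) return(integer(0))
      return(0:(L - len))
    }
    starts <- integer(0)
    for (br in pam$branches) {
      if (pam$orientation == "three_prime") {
        rx <- paste0("(?=", strrep(".", len + pam$gap), iupac_regex(br),
                     ")")
      } else {
        rx <- paste0("(?=", iupac_regex(br), strrep(".", pam$gap + len),
                     ")")
      }
      m <- gregexpr(rx, s, perl = TRUE)[[1]]
      m <- m[m > 0L]
      if (length(m)) {
        sp <- if (pam$orientation == "three_prime") m - 1L else
          m - 1L + nchar(br) + pam$gap
        starts <- c(starts, sp)
      }
    }
    sort(unique(starts))
  }
  fwd <- one(seq)
  rev_rc <- one(pangrna::reverse_complement(seq))
  rev <- sort(L - (rev_rc + len))
  list(fwd = fwd, rev = rev)
}

# exhaustive window-scan edit-distance oracle for off-target hits
# returns distinct loci with minimal edit distance <= max_edits
oracle_ot_loci <- function(spacer, subject, max_edits) {
  m <- nchar(spacer)
  n <- nchar(subject)
  loci <- list()
  for (w in max(1L, m - max_edits):(m + max_edits)) {
    if (w > n) next
    windows <- substring(subject, 1:(n - w + 1L), w:n)
    d <- drop(utils::adist(spacer, windows))
    hit <- which(d <= max_edits)
    for (s in hit)
      loci[[length(loci) + 1L]] <- c(start = s - 1L, end = s - 1L + w,
                                     edits = d[s])
  }
  if (!length(loci)) return(NULL)
  df <- as.data.frame(do.call(rbind, loci))
  # collapse overlapping loci, keeping the smallest-distance representative
  df <- df[order(df$start, df$edits), ]
  keep <- rep(TRUE, nrow(df))
  last_end <- -1L
  best_i <- NA
  groups <- integer(nrow(df))
  gid <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) gid <- gid + 1L
    groups[i] <- gid
    last_end <- max(last_end, df$end[i])
  }
  out <- do.call(rbind, lapply(split(df, groups), function(g)
    g[which.min(g$edits), ]))
  rownames(out) <- NULL
  out
}

# verdict oracle: does any unmasked locus (either strand) qualify under
# the clause pattern?  Events for a locus are derived with Biostrings
# global alignment under unit edit costs.
oracle_ot_events <- function(spacer, window) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 0,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(spacer, window, type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  m <- sum(p != "-")
  events <- integer(m)
  ins <- integer(m)
  i <- 0L
  for (col in seq_along(p)) {
    if (p[col] != "-" && s[col] != "-") {
      i <- i + 1L
      events[i] <- if (p[col] == s[col]) 0L else 1L
    } else if (p[col] != "-") {
      i <- i + 1L
      events[i] <- 2L
    } else {
      ins[min(i + 1L, m)] <- ins[min(i + 1L, m)] + 1L
    }
  }
  list(events = events, ins = ins)
}

oracle_clause_ok <- function(events, ins, max_count, types, from, to,
                             orientation) {
  m <- length(events)
  relpos <- if (orientation == "five_prime") -(1:m) else (1:m) - m - 1L
  if (is.na(to)) to <- -m
  w <- relpos <= from & relpos >= to
  cnt <- 0L
  if (grepl("m", types)) cnt <- cnt + sum(events[w] == 1L)
  if (grepl("g", types)) cnt <- cnt + sum(events[w] == 2L) + sum(ins[w])
  cnt <= max_count
}

oracle_ot_verdict <- function(spacer, backgrounds, masked, pattern,
                              max_edits, orientation = "three_prime") {
  for (sid in names(backgrounds)) {
    bg <- backgrounds[[sid]]
    L <- nchar(bg)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") bg else pangrna::reverse_complement(bg)
      loci <- oracle_ot_loci(spacer, subj, max_edits)
      if (is.null(loci)) next
      for (i in seq_len(nrow(loci))) {
        fs <- loci$start[i]; fe <- loci$end[i]
        if (strand == "-") { tmp <- L - fe; fe <- L - fs; fs <- tmp }
        is_masked <- FALSE
        if (!is.null(masked) && nrow(masked) > 0L) {
          sub <- masked[masked$seqid == sid, , drop = FALSE]
          is_masked <- any(sub$start < fe & sub$end > fs)
        }
        if (is_masked) next
        ev <- oracle_ot_events(spacer,
                               substr(subj, loci$start[i] + 1L,
                                      loci$end[i]))
        dangerous <- all(vapply(seq_len(nrow(pattern)), function(ci)
          oracle_clause_ok(ev$events, ev$ins, pattern$max_count[ci],
                           pattern$types[ci], pattern$from_pos[ci],
                           pattern$to_pos[ci], orientation), logical(1)))
        if (dangerous) return("fail")
      }
    }
  }
  "pass"
}

# exhaustive minimum set cover by subset enumeration in increasing size
oracle_min_cover_size <- function(sets, universe) {
  ids <- names(sets)
  for (k in seq_along(ids)) {
    for (comb in combn(ids, k, simplify = FALSE)) {
      if (setequal(intersect(
        unique(unlist(sets[comb], use.names = FALSE)), universe),
        universe))
        return(k)
    }
  }
  Inf
}

oracle_all_min_covers <- function(sets, universe) {
  k <- oracle_min_cover_size(sets, universe)
  if (!is.finite(k)) return(list())
  Filter(function(comb) setequal(
    intersect(unique(unlist(sets[comb], use.names = FALSE)), universe),
    universe),
    combn(names(sets), k, simplify = FALSE))
}

# random coverage instance for set-cover properties
random_cover_instance <- function(n_targets, n_grna, p = 0.35) {
  targets <- sprintf("t%02d", seq_len(n_targets))
  sets <- list()
  for (i in seq_len(n_grna)) {
    cov <- targets[runif(n_targets) < p]
    if (!length(cov)) cov <- sample(targets, 1L)
    sets[[sprintf("g%02d", i)]] <- sort(cov)
  }
  # guarantee coverability
  missing <- setdiff(targets, unique(unlist(sets, use.names = FALSE)))
  if (length(missing))
    sets[[sprintf("g%02d", n_grna)]] <-
      sort(unique(c(sets[[sprintf("g%02d", n_grna)]], missing)))
  sets
}

# copy of a spacer with a planted edit: "exact", "mismatch", or "gap".
# Gap copies delete a base whose neighbours differ so the alignment (and
# hence the event position) is unambiguous; spacers with no such position
# fall back to a mismatch copy.
mutated_copy <- function(spacer, kind) {
  chars <- strsplit(spacer, "")[[1]]
  if (kind == "exact") return(spacer)
  if (kind == "gap") {
    ok <- Filter(function(i) chars[i] != chars[i - 1] &&
                   chars[i] != chars[i + 1], 5:15)
    if (length(ok)) {
      i <- if (length(ok) == 1L) ok else sample(ok, 1L)
      return(paste(chars[-i], collapse = ""))
    }
    # fall through to a mismatch copy
  }
  i <- sample(length(chars), 1L)
  chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

coverage_from_sets <- function(sets, pos5_list = NULL) {
  rows <- list()
  for (g in names(sets)) {
    for (t in sets[[g]]) {
      p5 <- if (!is.null(pos5_list)) pos5_list[[g]][[t]] else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        grna_id = g, grna_seq = strrep("A", 20), target_id = t,
        start = p5, end = p5 + 20L, strand = "+", pam_site = ".",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[["check:GC"]] <- "pass"
  pangrna::build_coverage(pangrna:::as_grna_mapping(df))
}
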