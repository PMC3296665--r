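new_assembly <- function(contigs, scaffolds = NULL, source = "builtin") {
  if (is.null(scaffolds)) {
    scaffolds <- tibble(scaffold_id = character(), contig_id = character(),
                        position = integer(), orientation = character(),
                        gap_after = integer())
  }
  structure(list(contigs = contigs, scaffolds = scaffolds, source = source),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly: %d contigs (%s bp), %d scaffolds, source %s>\n",
              nrow(x$contigs), format(sum(x$contigs$length), big.mark = ","),
              length(unique(x$scaffolds$scaffold_id)), x$source))
  invisible(x)
}

#' @method glance assembly
#' @export
glance.assembly <- function(x, ...) {
  tibble(
    n_contigs = nrow(x$contigs),
    total_bp = sum(x$contigs$length),
    n50 = n50(x$contigs$length),
    n_scaffolds = length(unique(x$scaffolds$scaffold_id)),
    source = x$source
  )
}

#' Greedy overlap assembly of a read set
#'
#' A greedy overlap-layout-consensus assembler: reads are indexed by
#' minimizer seeds (both orientations, with adaptive masking of
#' high-occurrence repeat seeds), contigs grow by repeatedly appending the
#' highest-scoring verified suffix-prefix overlap (score = overlap length
#' x identity; ties broken deterministically), contained reads are placed
#' into the growing layout, and the consensus is a per-column majority
#' vote.  Extension stops at a branch: when a rival overlap within
#' `branch_margin` bases of the best one implies a conflicting
#' continuation (the signature of a repeat boundary), the contig is broken
#' there.  Contigs wholly contained in longer contigs are removed.
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param min_overlap Minimum suffix-prefix overlap in bases (>= 20).
#' @param min_identity Minimum overlap identity in `[0.8, 1]`.
#' @param seed_k,seed_w Minimizer k-mer size and window.
#' @param branch_margin Overlap-length margin within which a conflicting
#'   rival overlap breaks the contig.
#' @return An `assembly` with contigs and (initially) no scaffolds.
#' @export
greedy_assemble <- function(reads, min_overlap = 40, min_identity = 0.97,
                            seed_k = 15, seed_w = 5, branch_margin = 30) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (length(seqs) == 0) abort("empty read set")
  if (min_overlap < 20) abort("`min_overlap` must be >= 20")
  if (min_identity < 0.8 || min_identity > 1) {
    abort("`min_identity` must be in [0.8, 1]")
  }
  res <- cpp_greedy_assemble(seqs, as.integer(min_overlap), min_identity,
                             as.integer(seed_k), as.integer(seed_w),
                             as.integer(branch_margin))
  contigs <- as.character(res$contigs)
  new_assembly(tibble(
    contig_id = sprintf("ctg_%05d", seq_along(contigs)),
    sequence = contigs,
    length = nchar(contigs)
  ))
}

#' Order contigs into scaffolds with paired-end links
#'
#' Mates are anchored on contigs by unique k-mer voting.  An edge between
#' two contig ends requires at least `min_links` pairs agreeing in
#' relative orientation with a plausible implied gap; edges whose
#' orientation is disputed by 30% or more of their links are dropped.
#' Accepted edges are linearised into scaffolds (each contig end used at
#' most once, no cycles); the gap estimate is the median implied gap,
#' clamped at 1.
#'
#' @param assembly An `assembly`.
#' @param pairs A paired `read_set` (mate flags 1/2).
#' @param insert_mean,insert_sd Library fragment length in bases.
#' @param min_links Minimum supporting pairs per edge (>= 2).
#' @param k Anchor k-mer size for mate placement.
#' @return The assembly with a populated `scaffolds` table.
#' @export
scaffold <- function(assembly, pairs, insert_mean, insert_sd,
                     min_links = 3, k = 17) {
  if (min_links < 2) abort("`min_links` must be >= 2")
  if (!all(c(1L, 2L) %in% pairs$mate)) {
    abort("`pairs` must carry mate flags 1 and 2")
  }
  ctg <- assembly$contigs
  place <- cpp_place_reads(pairs$sequence, ctg$sequence, as.integer(k), 3L)
  pl <- tibble(
    pair_id = sub("/[12]$", "", pairs$read_id),
    mate = pairs$mate,
    contig = place$contig,
    pos = place$pos,
    pstrand = place$strand,
    read_len = nchar(pairs$sequence)
  ) |>
    filter(!is.na(.data$contig))

  if (nrow(pl) == 0) {
    warn("no mappable pairs; assembly returned unchanged")
    return(assembly)
  }

  links <- pl |>
    inner_join(pl, by = "pair_id", suffix = c("_1", "_2"),
               relationship = "many-to-many") |>
    filter(.data$mate_1 == 1L, .data$mate_2 == 2L,
           .data$contig_1 != .data$contig_2)
  if (nrow(links) == 0) {
    warn("no pairs link two contigs; assembly returned unchanged")
    return(assembly)
  }

  clen <- ctg$length
  links <- links |>
    mutate(
      flank_1 = ifelse(.data$pstrand_1 == "+",
                       clen[.data$contig_1] - .data$pos_1,
                       .data$pos_1 + .data$read_len_1),
      flank_2 = ifelse(.data$pstrand_2 == "+",
                       clen[.data$contig_2] - .data$pos_2,
                       .data$pos_2 + .data$read_len_2),
      end_1 = ifelse(.data$pstrand_1 == "+", "R", "L"),
      end_2 = ifelse(.data$pstrand_2 == "+", "R", "L"),
      gap = insert_mean - .data$flank_1 - .data$flank_2
    ) |>
    filter(.data$gap <= insert_mean + 3 * insert_sd,
           .data$gap >= -(3 * insert_sd + 1000)) |>
    mutate(
      a = pmin(.data$contig_1, .data$contig_2),
      b = pmax(.data$contig_1, .data$contig_2),
      end_a = ifelse(.data$contig_1 <= .data$contig_2, .data$end_1,
                     .data$end_2),
      end_b = ifelse(.data$contig_1 <= .data$contig_2, .data$end_2,
                     .data$end_1)
    )

  edges <- links |>
    count(.data$a, .data$b, .data$end_a, .data$end_b, name = "n_links") |>
    group_by(.data$a, .data$b) |>
    mutate(total = sum(.data$n_links)) |>
    slice_max(.data$n_links, n = 1, with_ties = FALSE) |>
    ungroup() |>
    filter(.data$n_links >= min_links,
           .data$n_links / .data$total > 0.7)

  if (nrow(edges) == 0) {
    warn("no contig pair has enough consistent links; nothing scaffolded")
    return(assembly)
  }

  gaps <- links |>
    semi_join(edges, by = c("a", "b", "end_a", "end_b")) |>
    group_by(.data$a, .data$b, .data$end_a, .data$end_b) |>
    summarise(gap_raw = round(median(.data$gap)),
              gap_estimate = max(1, round(median(.data$gap))),
              .groups = "drop")
  # adjacent contigs first: a long-insert link can also join contigs that
  # merely flank a short contig, and accepting such a skip-link would steal
  # the ends the true neighbours need
  edges <- edges |>
    inner_join(gaps, by = c("a", "b", "end_a", "end_b")) |>
    arrange(.data$gap_raw, desc(.data$n_links), .data$a, .data$b)

  # transitive reduction: drop an A-C edge explained by A-B plus B-C
  if (nrow(edges) > 2) {
    tol <- 3 * insert_sd + 1000
    # half-edge view: one row per (contig, end) incidence
    he <- function(i) {
      tibble(edge = i,
             contig = c(edges$a[i], edges$b[i]),
             end = c(edges$end_a[i], edges$end_b[i]),
             other = c(edges$b[i], edges$a[i]),
             other_end = c(edges$end_b[i], edges$end_a[i]))
    }
    half <- bind_rows(lapply(seq_len(nrow(edges)), he))
    opposite <- function(e) ifelse(e == "L", "R", "L")
    drop <- rep(FALSE, nrow(edges))
    for (i in seq_len(nrow(edges))) {
      # edge i joins (A, endA) to (C, endC); look for a middle contig B
      A <- edges$a[i]; endA <- edges$end_a[i]
      C <- edges$b[i]; endC <- edges$end_b[i]
      j_rows <- half |>
        filter(.data$contig == A, .data$end == endA,
               .data$edge != i, .data$other != C)
      for (jr in seq_len(nrow(j_rows))) {
        B <- j_rows$other[jr]
        endB_far <- opposite(j_rows$other_end[jr])
        k_rows <- half |>
          filter(.data$contig == B, .data$end == endB_far,
                 .data$other == C, .data$other_end == endC)
        if (nrow(k_rows) == 0) next
        implied <- edges$gap_raw[j_rows$edge[jr]] + clen[B] +
          edges$gap_raw[k_rows$edge[1]]
        if (abs(implied - edges$gap_raw[i]) <= tol) drop[i] <- TRUE
      }
    }
    edges <- edges[!drop, , drop = FALSE]
  }

  # A contig end courted by several partners with comparable support sits
  # in collapsed repeat sequence.  Such hub contigs are removed from the
  # graph altogether: their flanks are then free to join straight across
  # the repeat through fragment-spanning links (which only a sufficiently
  # long insert provides).  Afterwards, remaining multi-partner ends keep
  # only their dominant (>= 2x runner-up) edge.
  if (nrow(edges) > 1) {
    end_table <- function(e) {
      bind_rows(
        e |> mutate(edge = row_number()) |>
          transmute(.data$edge, contig = .data$a, end = .data$end_a,
                    .data$n_links),
        e |> mutate(edge = row_number()) |>
          transmute(.data$edge, contig = .data$b, end = .data$end_b,
                    .data$n_links))
    }
    hubs <- end_table(edges) |>
      group_by(.data$contig, .data$end) |>
      arrange(desc(.data$n_links), .by_group = TRUE) |>
      summarise(contested = n() >= 2 &&
                  first(.data$n_links) < 2 * nth(.data$n_links, 2),
                .groups = "drop") |>
      filter(.data$contested) |>
      pull(.data$contig) |>
      unique()
    # demote hub edges: spanning links get first pick of the ends, hub
    # edges only serve ends nothing else can join
    edges <- edges |>
      mutate(tier = ifelse(.data$a %in% hubs | .data$b %in% hubs, 2L, 1L))
    if (nrow(edges) > 1) {
      keep <- rep(TRUE, nrow(edges))
      et <- end_table(edges) |>
        left_join(edges |> mutate(edge = row_number()) |>
                    select("edge", "tier"), by = "edge")
      for (grp in split(et, paste(et$contig, et$end, et$tier))) {
        if (nrow(grp) < 2) next
        grp <- grp |> arrange(desc(.data$n_links), .data$edge)
        keep[grp$edge[-1]] <- FALSE
      }
      edges <- edges[keep, , drop = FALSE]
    }
    edges <- edges |>
      arrange(.data$tier, .data$gap_raw, desc(.data$n_links),
              .data$a, .data$b)
  }
  if (nrow(edges) == 0) {
    warn("all candidate edges were ambiguous; nothing scaffolded")
    return(assembly)
  }

  # greedy edge acceptance: each contig end used once, no cycles
  n <- nrow(ctg)
  end_used <- matrix(FALSE, n, 2, dimnames = list(NULL, c("L", "R")))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  accepted <- list()
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (end_used[e$a, e$end_a] || end_used[e$b, e$end_b]) next
    ra <- find(e$a); rb <- find(e$b)
    if (ra == rb) next
    parent[ra] <- rb
    end_used[e$a, e$end_a] <- TRUE
    end_used[e$b, e$end_b] <- TRUE
    accepted[[length(accepted) + 1]] <- e
  }
  if (length(accepted) == 0) {
    warn("all candidate edges conflicted; nothing scaffolded")
    return(assembly)
  }
  acc <- bind_rows(accepted)

  # adjacency: for each contig, neighbour via each end
  nbr <- array(NA_integer_, dim = c(n, 2), dimnames = list(NULL, c("L", "R")))
  nbr_end <- array(NA_character_, dim = c(n, 2),
                   dimnames = list(NULL, c("L", "R")))
  nbr_gap <- array(NA_integer_, dim = c(n, 2),
                   dimnames = list(NULL, c("L", "R")))
  for (i in seq_len(nrow(acc))) {
    e <- acc[i, ]
    nbr[e$a, e$end_a] <- e$b; nbr_end[e$a, e$end_a] <- e$end_b
    nbr_gap[e$a, e$end_a] <- e$gap_estimate
    nbr[e$b, e$end_b] <- e$a; nbr_end[e$b, e$end_b] <- e$end_a
    nbr_gap[e$b, e$end_b] <- e$gap_estimate
  }

  in_scaffold <- rep(FALSE, n)
  scaffolds <- list()
  sc_id <- 0
  for (start in seq_len(n)) {
    if (in_scaffold[start]) next
    if (is.na(nbr[start, "L"]) && is.na(nbr[start, "R"])) next
    # walk to the leftmost contig of the chain
    cur <- start; enter <- "L"
    repeat {
      prev <- nbr[cur, enter]
      if (is.na(prev) || in_scaffold[prev]) break
      enter_prev <- nbr_end[cur, enter]
      nxt_enter <- if (enter_prev == "L") "R" else "L"
      cur <- prev; enter <- nxt_enter
      if (cur == start) break  # cycle; start anywhere
    }
    sc_id <- sc_id + 1
    rows <- list()
    pos <- 0
    # traverse right; `enter` is the end we came in through, so orientation
    # "+" means entered via L
    repeat {
      if (in_scaffold[cur]) break
      in_scaffold[cur] <- TRUE
      ori <- if (enter == "L") "+" else "-"
      exit <- if (enter == "L") "R" else "L"
      nxt <- nbr[cur, exit]
      gap <- nbr_gap[cur, exit]
      pos <- pos + 1
      rows[[pos]] <- tibble(
        scaffold_id = sprintf("scf_%04d", sc_id),
        contig_id = ctg$contig_id[cur],
        position = pos, orientation = ori,
        gap_after = if (!is.na(nxt) && !in_scaffold[nxt])
          as.integer(gap) else NA_integer_)
      if (is.na(nxt) || in_scaffold[nxt]) break
      enter <- nbr_end[cur, exit]
      cur <- nxt
    }
    scaffolds[[sc_id]] <- bind_rows(rows)
  }
  assembly$scaffolds <- bind_rows(scaffolds)
  assembly
}

#' Scaffold sequences (contigs joined by N gaps)
#'
#' @param assembly An `assembly` with scaffolds.
#' @return Named character vector: one sequence per scaffold (contigs
#'   joined by runs of N of the estimated gap length) plus unplaced
#'   contigs under their own names.
#' @export
scaffold_sequences <- function(assembly) {
  ctg <- setNames(assembly$contigs$sequence, assembly$contigs$contig_id)
  out <- character()
  if (nrow(assembly$scaffolds) > 0) {
    for (sid in unique(assembly$scaffolds$scaffold_id)) {
      rows <- assembly$scaffolds |>
        filter(.data$scaffold_id == sid) |>
        arrange(.data$position)
      pieces <- character(0)
      for (i in seq_len(nrow(rows))) {
        s <- ctg[[rows$contig_id[i]]]
        if (rows$orientation[i] == "-") s <- cpp_revcomp(s)[[1]]
        pieces <- c(pieces, s)
        if (!is.na(rows$gap_after[i]) && i < nrow(rows)) {
          pieces <- c(pieces, strrep("N", rows$gap_after[i]))
        }
      }
      out[sid] <- paste(pieces, collapse = "")
    }
  }
  unplaced <- setdiff(assembly$contigs$contig_id,
                      assembly$scaffolds$contig_id)
  c(out, ctg[unplaced])
}

#' Ingest an externally produced assembly
#'
#' Without an AGP file, each FASTA record is split at runs of 10 or more
#' N's into contigs grouped as one scaffold per record (records without N
#' runs become singleton scaffolds).  With an AGP v2.0 file, the scaffold
#' structure follows the AGP rows exactly and the FASTA must contain the
#' component contigs.
#'
#' @param fasta_path Assembly FASTA.
#' @param agp_path Optional AGP v2.0 file.
#' @return An `assembly` with `source = "external"`.
#' @export
ingest_assembly <- function(fasta_path, agp_path = NULL) {
  recs <- read_fasta(fasta_path)
  if (is.null(agp_path)) {
    contigs <- list(); scaff <- list()
    for (rn in names(recs)) {
      parts <- strsplit(recs[[rn]], "N{10,}")[[1]]
      gaps <- regmatches(recs[[rn]], gregexpr("N{10,}", recs[[rn]]))[[1]]
      ids <- if (length(parts) == 1) rn else
        sprintf("%s_c%d", rn, seq_along(parts))
      contigs[[rn]] <- tibble(contig_id = ids, sequence = parts,
                              length = nchar(parts))
      scaff[[rn]] <- tibble(
        scaffold_id = rn, contig_id = ids,
        position = seq_along(ids), orientation = "+",
        gap_after = c(as.integer(nchar(gaps)),
                      NA_integer_)[seq_along(ids)])
    }
    return(new_assembly(bind_rows(contigs), bind_rows(scaff), "external"))
  }
  lines <- readLines(agp_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      abort(sprintf("malformed AGP line %d: fewer than 8 fields", i))
    }
    if (f[5] %in% c("N", "U")) {
      rows[[i]] <- tibble(object = f[1], type = f[5],
                          gap = as.integer(f[6]), component = NA_character_,
                          orientation = NA_character_)
    } else {
      if (length(f) < 9) {
        abort(sprintf("malformed AGP line %d: component row needs 9 fields", i))
      }
      if (!f[6] %in% names(recs)) {
        abort(sprintf("AGP line %d references absent contig '%s'", i, f[6]))
      }
      rows[[i]] <- tibble(object = f[1], type = f[5],
                          gap = NA_integer_, component = f[6],
                          orientation = f[9])
    }
  }
  agp <- bind_rows(rows)
  comp <- agp |> filter(!is.na(.data$component))
  contigs <- tibble(contig_id = comp$component,
                    sequence = unname(recs[comp$component]),
                    length = nchar(unname(recs[comp$component])))
  scaff <- list()
  for (obj in unique(agp$object)) {
    a <- agp |> filter(.data$object == obj)
    pos <- 0; rws <- list()
    pending_gap <- NA_integer_
    for (i in seq_len(nrow(a))) {
      if (!is.na(a$gap[i])) { pending_gap <- a$gap[i]; next }
      if (pos > 0) rws[[pos]]$gap_after <- pending_gap
      pos <- pos + 1
      rws[[pos]] <- tibble(scaffold_id = obj, contig_id = a$component[i],
                           position = pos,
                           orientation = ifelse(a$orientation[i] == "-",
                                                "-", "+"),
                           gap_after = NA_integer_)
      pending_gap <- NA_integer_
    }
    scaff[[obj]] <- bind_rows(rws)
  }
  new_assembly(contigs, bind_rows(scaff), "external")
}

#' Write an assembly to FASTA and AGP
#'
#' @param assembly An `assembly`.
#' @param dir Output directory.
#' @param name File stem.
#' @export
write_assembly <- function(assembly, dir, name = "assembly") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(assembly$contigs$sequence,
                       assembly$contigs$contig_id),
              file.path(dir, paste0(name, ".contigs.fasta")))
  write_fasta(scaffold_sequences(assembly),
              file.path(dir, paste0(name, ".scaffolds.fasta")))
  # AGP v2.0
  lines <- c("##agp-version\t2.0")
  clen <- setNames(assembly$contigs$length, assembly$contigs$contig_id)
  if (nrow(assembly$scaffolds) > 0) {
    for (sid in unique(assembly$scaffolds$scaffold_id)) {
      rows <- assembly$scaffolds |>
        filter(.data$scaffold_id == sid) |>
        arrange(.data$position)
      at <- 1; part <- 0
      for (i in seq_len(nrow(rows))) {
        cl <- clen[[rows$contig_id[i]]]
        part <- part + 1
        lines <- c(lines, paste(sid, at, at + cl - 1, part, "W",
                                rows$contig_id[i], 1, cl,
                                rows$orientation[i], sep = "\t"))
        at <- at + cl
        if (!is.na(rows$gap_after[i]) && i < nrow(rows)) {
          part <- part + 1
          lines <- c(lines, paste(sid, at, at + rows$gap_after[i] - 1,
                                  part, "N", rows$gap_after[i],
                                  "scaffold", "yes", "paired-ends",
                                  sep = "\t"))
          at <- at + rows$gap_after[i]
        }
      }
    }
  }
  writeLines(lines, file.path(dir, paste0(name, ".agp")))
  invisible(dir)
}
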