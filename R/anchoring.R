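#' Assign a scaffold to a reference chromosome by homology consensus
#'
#' The consensus chromosome is the modal chromosome among the scaffold's
#' homology hits; hits on the consensus chromosome farther than
#' `max_gap` from their nearest same-group neighbour are discarded as
#' outliers; the anchor position is the median retained reference
#' position, and the orientation is the sign consensus of colinearity
#' between the query order (the order hits are supplied in, i.e. gene
#' order along the scaffold) and the reference positions.
#'
#' @param hits data.frame with columns `query_gene_id`, `scaffold_id`,
#'   `reference_chromosome`, `reference_position`, `reference_strand`,
#'   `score`, all for one scaffold, rows ordered by gene position along
#'   the scaffold.
#' @param max_gap neighbour fence in bp (default 1e6): retained genes must
#'   lie within this distance of another retained gene.
#' @return one-row data.frame (`scaffold_id`, `chromosome`,
#'   `anchor_position`, `orientation`, `n_supporting_genes`, `reason`);
#'   a modal-chromosome tie yields `chromosome = "unplaced"`.
#' @export
assign_scaffold <- function(hits, max_gap = 1e6) {
  check_columns(hits, c("query_gene_id", "scaffold_id",
                        "reference_chromosome", "reference_position"),
                "hits")
  if (!nrow(hits)) stop("at least one homology hit is required", call. = FALSE)
  if (length(unique(hits$scaffold_id)) != 1L)
    stop("`hits` must describe a single scaffold", call. = FALSE)
  if (any(hits$reference_position < 0)) stop_field("reference_position", "must be >= 0")
  sid <- hits$scaffold_id[1]

  counts <- sort(table(hits$reference_chromosome), decreasing = TRUE)
  if (length(counts) > 1L && counts[1] == counts[2])
    return(data.frame(scaffold_id = sid, chromosome = "unplaced",
                      anchor_position = NA_real_, orientation = "unknown",
                      n_supporting_genes = 0L,
                      reason = "modal chromosome tie",
                      stringsAsFactors = FALSE))
  chrom <- names(counts)[1]
  grp <- hits[hits$reference_chromosome == chrom, , drop = FALSE]

  # prune genes with no retained neighbour within max_gap (single pass)
  if (nrow(grp) > 1L) {
    pos <- grp$reference_position
    nn <- vapply(seq_along(pos), function(i) min(abs(pos[-i] - pos[i])),
                 numeric(1))
    grp <- grp[nn <= max_gap, , drop = FALSE]
    if (!nrow(grp))  # mutually distant genes: fall back to all, unoriented
      return(data.frame(scaffold_id = sid, chromosome = "unplaced",
                        anchor_position = NA_real_, orientation = "unknown",
                        n_supporting_genes = 0L,
                        reason = "no mutually close genes on consensus chromosome",
                        stringsAsFactors = FALSE))
  }

  orientation <- "unknown"
  if (nrow(grp) > 1L) {
    pos <- grp$reference_position
    pairs <- utils::combn(seq_along(pos), 2)
    d <- sign(pos[pairs[2, ]] - pos[pairs[1, ]])  # query order = row order
    up <- sum(d > 0); down <- sum(d < 0)
    if (up > down) orientation <- "+"
    else if (down > up) orientation <- "-"
  } else if (nrow(grp) == 1L && "reference_strand" %in% names(grp)) {
    orientation <- as.character(grp$reference_strand[1])
  }

  data.frame(scaffold_id = sid, chromosome = chrom,
             anchor_position = stats::median(grp$reference_position),
             orientation = orientation,
             n_supporting_genes = nrow(grp), reason = "",
             stringsAsFactors = FALSE)
}

#' Assign many scaffolds from one hit table
#'
#' @param hits homology-hit data.frame for any number of scaffolds.
#' @param max_gap see [assign_scaffold()].
#' @return data.frame with one row per scaffold.
#' @export
assign_scaffolds <- function(hits, max_gap = 1e6) {
  parts <- split(hits, hits$scaffold_id)
  out <- do.call(rbind, lapply(parts, assign_scaffold, max_gap = max_gap))
  rownames(out) <- NULL
  out
}

#' Concatenate anchored scaffolds into a pseudochromosome coordinate map
#'
#' Scaffolds placed on one chromosome are ordered by anchor position and
#' laid end to end; the resulting map converts scaffold-local coordinates
#' (0-based) to pseudochromosome coordinates and back.
#'
#' @param assignments data.frame from [assign_scaffold()] rows, all on one
#'   chromosome.
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @return object of class `pseudochromosome`: list with `map` (data.frame
#'   `scaffold_id`, `chromosome`, `offset`, `length`, `orientation`),
#'   `to_pseudo(scaffold_id, pos)` and `to_scaffold(pos)` functions.
#' @export
build_pseudochromosome <- function(assignments, scaffold_lengths) {
  check_columns(assignments, c("scaffold_id", "chromosome", "anchor_position"),
                "assignments")
  if (anyDuplicated(assignments$scaffold_id))
    stop("duplicate scaffold ids in assignments", call. = FALSE)
  chrom <- unique(assignments$chromosome)
  if (length(chrom) != 1L)
    stop("all assignments must be on a single chromosome", call. = FALSE)
  missing <- setdiff(assignments$scaffold_id, names(scaffold_lengths))
  if (length(missing))
    stop(sprintf("missing length for scaffold(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ord <- order(assignments$anchor_position, assignments$scaffold_id)
  a <- assignments[ord, , drop = FALSE]
  lens <- as.numeric(scaffold_lengths[a$scaffold_id])
  offsets <- cumsum(c(0, head(lens, -1)))
  map <- data.frame(scaffold_id = a$scaffold_id, chromosome = chrom,
                    offset = offsets, length = lens,
                    orientation = if ("orientation" %in% names(a))
                      a$orientation else "unknown",
                    stringsAsFactors = FALSE)
  to_pseudo <- function(scaffold_id, pos) {
    i <- match(scaffold_id, map$scaffold_id)
    if (anyNA(i)) stop("unknown scaffold id", call. = FALSE)
    if (any(pos < 0 | pos >= map$length[i]))
      stop("position outside scaffold", call. = FALSE)
    map$offset[i] + pos
  }
  to_scaffold <- function(pos) {
    if (any(pos < 0 | pos >= sum(map$length)))
      stop("position outside pseudochromosome", call. = FALSE)
    i <- findInterval(pos, map$offset)
    data.frame(scaffold_id = map$scaffold_id[i], pos = pos - map$offset[i],
               stringsAsFactors = FALSE)
  }
  structure(list(map = map, to_pseudo = to_pseudo, to_scaffold = to_scaffold),
            class = "pseudochromosome")
}

#' @export
print.pseudochromosome <- function(x, ...) {
  cat(sprintf("pseudochromosome %s: %d scaffolds, %.0f bp\n",
              x$map$chromosome[1], nrow(x$map), sum(x$map$length)))
  invisible(x)
}
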