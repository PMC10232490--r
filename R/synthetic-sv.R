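new_sv_table <- function(n = 0) {
  data.frame(sample_id = character(n), chrom1 = character(n),
             pos1 = integer(n), chrom2 = character(n), pos2 = integer(n),
             sv_type = character(n), size = integer(n),
             orientation = character(n), clustered = logical(n),
             stringsAsFactors = FALSE)
}

parse_sv_channel <- function(channel) {
  parts <- strsplit(channel, "/", fixed = TRUE)
  ty <- vapply(parts, `[`, character(1), 1)
  clustered <- vapply(parts, function(p) p[length(p)] == "clustered",
                      logical(1))
  bin <- ifelse(ty == "tra", NA_character_,
                vapply(parts, `[`, character(1), 2))
  data.frame(type = ty, bin = bin, clustered = clustered,
             stringsAsFactors = FALSE)
}

#' Simulate structural variants from 32-class weights
#'
#' Each SV is drawn from the 32-class scheme (type x size bin x
#' clustered). Sizes are log-uniform within the class size bin (the open
#' top bin is capped at 50 Mb). SVs from clustered classes place their
#' first breakend inside a single bin-aligned 1 Mb window of
#' `clustered_region`, so a plan with >= 5 clustered SVs plants >= 10
#' breakpoints in one window; all other SVs are placed uniformly
#' (chromosome chosen proportional to length). Inversions receive a
#' random head-to-head/tail-to-tail orientation.
#'
#' @param genome a `genome_model`.
#' @param class_weights 32-simplex over [sv_channels()].
#' @param n_sv number of SVs.
#' @param clustered_region NULL or list/data.frame with `chrom`, `start`,
#'   `end`; required if any clustered class has positive weight.
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return data.frame of SV records; `clustered` is NA until
#'   [flag_clustered_breakpoints()] is applied.
#' @export
simulate_svs <- function(genome, class_weights, n_sv,
                         clustered_region = NULL, seed = 1,
                         sample_id = "S1") {
  stopifnot(inherits(genome, "genome_model"))
  ch <- sv_channels()
  if (length(class_weights) != 32) stop("class_weights must have length 32")
  assert_simplex(class_weights, "class_weights")
  if (n_sv < 0) stop("n_sv must be >= 0")
  if (n_sv == 0) return(new_sv_table(0))
  info_all <- parse_sv_channel(ch)
  clustered_mass <- sum(class_weights[info_all$clustered])
  if (clustered_mass > 0 && is.null(clustered_region)) {
    stop("clustered_region is required when clustered classes have weight")
  }
  lens <- genome$chromosomes$length
  with_seed(seed, {
    chan <- sample(ch, n_sv, replace = TRUE, prob = class_weights)
    info <- parse_sv_channel(chan)
    size <- rep(NA_integer_, n_sv)
    intra <- info$type != "tra"
    if (any(intra)) {
      lo <- SV_SIZE_BREAKS[match(info$bin[intra], SV_SIZE_LABELS)]
      hi <- SV_SIZE_BREAKS[match(info$bin[intra], SV_SIZE_LABELS) + 1]
      hi[!is.finite(hi)] <- 5e7
      size[intra] <- as.integer(round(exp(stats::runif(sum(intra),
                                                       log(lo), log(hi - 1)))))
    }
    chrom1 <- character(n_sv); pos1 <- integer(n_sv)
    chrom2 <- character(n_sv); pos2 <- integer(n_sv)
    in_window <- info$clustered
    if (any(in_window)) {
      w0 <- floor(clustered_region$start / 1e6) * 1e6
      wlo <- max(w0 + 1, clustered_region$start)
      whi <- w0 + 1e6
      chrom1[in_window] <- clustered_region$chrom
      pos1[in_window] <- as.integer(floor(stats::runif(sum(in_window),
                                                       wlo, whi)))
    }
    if (any(!in_window)) {
      k <- sum(!in_window)
      ci <- sample(seq_along(lens), k, replace = TRUE,
                   prob = lens / sum(lens))
      chrom1[!in_window] <- genome$chromosomes$chrom[ci]
    }
    # cap sizes at the carrying chromosome and place the second breakend
    L1 <- lens[match(chrom1, genome$chromosomes$chrom)]
    size <- as.integer(pmin(size, L1 - 2))
    if (any(!in_window)) {
      k <- sum(!in_window)
      room <- L1[!in_window] -
        ifelse(is.na(size[!in_window]), 1L, size[!in_window]) - 1
      pos1[!in_window] <- 1L + as.integer(floor(stats::runif(k) *
                                                  pmax(room, 1)))
    }
    chrom2 <- chrom1
    pos2 <- pos1 + ifelse(is.na(size), 0L, size)
    tra <- info$type == "tra"
    if (any(tra)) {
      for (i in which(tra)) {
        others <- setdiff(seq_along(lens),
                          match(chrom1[i], genome$chromosomes$chrom))
        j <- if (length(others) == 1) others else sample(others, 1)
        chrom2[i] <- genome$chromosomes$chrom[j]
        pos2[i] <- 1L + as.integer(floor(stats::runif(1) * (lens[j] - 1)))
      }
    }
    # keep intra-chromosomal SVs inside the chromosome
    Lmax <- lens[match(chrom1, genome$chromosomes$chrom)]
    over <- intra & pos2 > Lmax
    if (any(over)) {
      shift <- pos2[over] - Lmax[over]
      pos1[over] <- pmax(1L, pos1[over] - as.integer(shift))
      pos2[over] <- pos1[over] + size[over]
    }
    orientation <- rep(NA_character_, n_sv)
    inv <- info$type == "inv"
    if (any(inv)) {
      orientation[inv] <- sample(c("h2h", "t2t"), sum(inv), replace = TRUE)
    }
  })
  type_map <- c(del = "DEL", dup = "DUP", inv = "INV", tra = "TRA")
  out <- data.frame(
    sample_id = sample_id, chrom1 = chrom1, pos1 = pos1,
    chrom2 = chrom2, pos2 = pos2,
    sv_type = unname(type_map[info$type]),
    size = ifelse(info$type == "tra", NA_integer_, size),
    orientation = orientation,
    clustered = NA,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
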