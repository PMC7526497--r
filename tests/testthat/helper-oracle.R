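# Independent oracle for the split caller: exhaustive gapless enumeration
# over (prefix length, insertion length, donor_end, acceptor_start). Written
# in plain R, independent of the package's DP path.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# microhomology by direct character extension (independent of the package)
oracle_mh <- function(donor, de, acceptor, as_) {
  dv <- strsplit(donor, "")[[1]]; av <- strsplit(acceptor, "")[[1]]
  l <- 0
  while (de - l - 1 >= 0 && as_ - l - 1 >= 0 &&
         dv[de - l] == av[as_ - l] && dv[de - l] != "N") l <- l + 1
  r <- 0
  while (de + r < length(dv) && as_ + r < length(av) &&
         dv[de + r + 1] == av[as_ + r + 1] && dv[de + r + 1] != "N") r <- r + 1
  l + r
}

# per prefix length: best gapless semi-global score over all reference end
# positions, plus the argmax set of end positions
oracle_flank <- function(qv, rv, match, mismatch) {
  L <- length(qv); m <- length(rv)
  best <- rep(-Inf, L); ends <- vector("list", L)
  for (d in 0:(m - 1)) {
    tmax <- min(L, m - d)
    if (tmax < 1) next
    hits <- qv[1:tmax] == rv[(1:tmax) + d]
    cs <- cumsum(hits)
    sc <- cs * match + ((1:tmax) - cs) * mismatch
    for (i in 1:tmax) {
      if (sc[i] > best[i] + 1e-9) {
        best[i] <- sc[i]; ends[[i]] <- i + d
      } else if (sc[i] == best[i]) {
        ends[[i]] <- c(ends[[i]], i + d)
      }
    }
  }
  list(best = best, ends = ends)
}

# full enumeration of all optimal splits; returns best total score and the
# maximal microhomology over all optimal placements (the caller's tie-break)
oracle_call <- function(read, donor, acceptor, mf, match = 1, mismatch = -2) {
  qv <- strsplit(read, "")[[1]]; L <- length(qv)
  dv <- strsplit(donor, "")[[1]]; av <- strsplit(acceptor, "")[[1]]
  D <- oracle_flank(qv, dv, match, mismatch)
  Arev <- oracle_flank(rev(qv), rev(av), match, mismatch)
  best <- -Inf; cands <- list()
  for (i in mf:(L - mf)) {
    if (D$best[i] <= 0) next
    for (k0 in i:(L - mf)) {
      if (Arev$best[L - k0] <= 0) next
      tot <- D$best[i] + Arev$best[L - k0]
      if (tot > best + 1e-9) {
        best <- tot; cands <- list(list(i = i, k0 = k0))
      } else if (tot == best) {
        cands <- c(cands, list(list(i = i, k0 = k0)))
      }
    }
  }
  if (!is.finite(best)) return(list(score = NA_real_, mh = NA_integer_))
  mh_best <- -1L
  for (cd in cands) {
    if (cd$k0 > cd$i) { mh_best <- max(mh_best, 0L); next }
    for (e in D$ends[[cd$i]]) {
      for (arev in Arev$ends[[L - cd$k0]]) {
        a <- length(av) - arev
        mh_best <- max(mh_best, oracle_mh(donor, e, acceptor, a))
      }
    }
  }
  list(score = best, mh = mh_best)
}

# a random junction instance: random references, read constructed as donor
# prefix (+ optional insertion) + acceptor suffix, with an optional single
# substitution
oracle_instance <- function() {
  nd <- sample(40:80, 1); na <- sample(40:80, 1)
  donor <- rand_seq(nd); acceptor <- rand_seq(na)
  f1 <- sample(15:25, 1); f2 <- sample(15:25, 1)
  de <- sample(f1:nd, 1); as_ <- sample(0:(na - f2), 1)
  ins <- if (runif(1) < 0.5) rand_seq(sample(1:4, 1)) else ""
  read <- paste0(substr(donor, de - f1 + 1, de), ins,
                 substr(acceptor, as_ + 1, as_ + f2))
  if (runif(1) < 0.5) {
    ch <- strsplit(read, "")[[1]]
    p <- sample(length(ch), 1)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    read <- paste(ch, collapse = "")
  }
  list(read = read, donor = donor, acceptor = acceptor)
}

# agreement of caller and oracle on n random instances; returns fraction
oracle_agreement <- function(n, params = caller_params(min_flank = 15)) {
  ok <- 0L
  for (i in seq_len(n)) {
    inst <- oracle_instance()
    call <- call_breakpoint(inst$read, inst$donor, inst$acceptor, params)
    ora <- oracle_call(inst$read, inst$donor, inst$acceptor,
                       params$min_flank, params$match, params$mismatch)
    agree <- if (is.na(ora$score)) {
      !call$callable
    } else {
      call$callable && call$score == ora$score && call$mh_len == ora$mh
    }
    ok <- ok + agree
  }
  ok / n
}

# small repeat-rich reference pair shared by several tests
demo_refs <- function(donor_len = 600, acceptor_len = 1200) {
  list(
    donor = make_switch_reference(donor_len, c("GAGCT", "GGGCT"), 0.1,
                                  seed = 101, name = "Smu", role = "donor"),
    acceptor = make_switch_reference(acceptor_len, c("TGGGG", "TGAGC"), 0.1,
                                     seed = 102, name = "Salpha",
                                     role = "acceptor"))
}
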