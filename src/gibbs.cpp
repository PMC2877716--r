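#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Collapsed ZOOPS Gibbs sampler inner loop.
//
// enc_f:  per-sequence integer vectors, bases coded 1..4 (A,C,G,T)
// bg_f:   per-sequence log2 background prob of the forward W-window at each
//         0-based offset
// bg_r:   same, for the minus-strand site covering the same forward offsets
// init_off / init_str: starting assignment (offset 0-based, -1 = absent;
//         strand 0 = plus, 1 = minus)
//
// One iteration withholds sequence (it % n), rebuilds the count matrix
// without it, and resamples its site across offsets x strands x absent.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_run(List enc_f, List bg_f, List bg_r, int W, int iterations,
               double pseudocount, double absent_prior,
               IntegerVector init_off, IntegerVector init_str) {
  const int n = enc_f.size();
  std::vector<std::vector<int> > seqs(n);
  std::vector<std::vector<double> > bgf(n), bgr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector e = enc_f[i];
    seqs[i].assign(e.begin(), e.end());
    NumericVector bf = bg_f[i], br = bg_r[i];
    bgf[i].assign(bf.begin(), bf.end());
    bgr[i].assign(br.begin(), br.end());
  }

  std::vector<int> off(init_off.begin(), init_off.end());
  std::vector<int> str(init_str.begin(), init_str.end());

  // site base (0..3) at motif column j for sequence i under assignment
  auto site_base = [&](int i, int o, int s, int j) -> int {
    if (s == 0) return seqs[i][o + j] - 1;
    return 4 - seqs[i][o + W - 1 - j];  // complement of mirrored position
  };

  std::vector<std::vector<double> > counts(W, std::vector<double>(4, 0.0));
  int n_assigned = 0;
  for (int i = 0; i < n; ++i) {
    if (off[i] < 0) continue;
    ++n_assigned;
    for (int j = 0; j < W; ++j) counts[j][site_base(i, off[i], str[i], j)] += 1.0;
  }

  const double ln2 = std::log(2.0);
  std::vector<double> lpfm(W * 4);
  std::vector<double> logw;

  // complete-data score (nats) of the current assignment shifted by delta:
  // sum over sites of log P(site | PFM of shifted sites) - log P(site | bg)
  auto shifted_score = [&](int delta, bool &valid) -> double {
    std::vector<std::vector<double> > cts(W, std::vector<double>(4, 0.0));
    int m = 0;
    valid = true;
    for (int i = 0; i < n; ++i) {
      if (off[i] < 0) continue;
      int o = off[i] + (str[i] == 0 ? delta : -delta);
      int noff_i = (int)seqs[i].size() - W + 1;
      if (o < 0 || o >= noff_i) { valid = false; return 0.0; }
      ++m;
      for (int j = 0; j < W; ++j) cts[j][site_base(i, o, str[i], j)] += 1.0;
    }
    if (m == 0) { valid = false; return 0.0; }
    double tot = m + 4.0 * pseudocount, sc = 0.0;
    std::vector<double> lp(W * 4);
    for (int j = 0; j < W; ++j)
      for (int b = 0; b < 4; ++b)
        lp[j * 4 + b] = std::log((cts[j][b] + pseudocount) / tot);
    for (int i = 0; i < n; ++i) {
      if (off[i] < 0) continue;
      int o = off[i] + (str[i] == 0 ? delta : -delta);
      for (int j = 0; j < W; ++j) sc += lp[j * 4 + site_base(i, o, str[i], j)];
      sc -= ln2 * (str[i] == 0 ? bgf[i][o] : bgr[i][o]);
    }
    return sc;
  };

  for (int it = 0; it < iterations; ++it) {
    int i = it % n;
    // withhold sequence i
    if (off[i] >= 0) {
      for (int j = 0; j < W; ++j) counts[j][site_base(i, off[i], str[i], j)] -= 1.0;
      --n_assigned;
      off[i] = -1;
    }
    const double tot = n_assigned + 4.0 * pseudocount;
    for (int j = 0; j < W; ++j)
      for (int b = 0; b < 4; ++b)
        lpfm[j * 4 + b] = std::log((counts[j][b] + pseudocount) / tot);  // natural log

    const int L = (int)seqs[i].size();
    const int noff = L - W + 1;
    logw.assign(2 * noff + 1, 0.0);
    const double site_prior = std::log(1.0 - absent_prior) - std::log(2.0 * noff);
    for (int o = 0; o < noff; ++o) {
      double lf = 0.0, lr = 0.0;
      for (int j = 0; j < W; ++j) {
        lf += lpfm[j * 4 + (seqs[i][o + j] - 1)];
        lr += lpfm[j * 4 + (4 - seqs[i][o + W - 1 - j])];
      }
      logw[o] = site_prior + lf - ln2 * bgf[i][o];
      logw[noff + o] = site_prior + lr - ln2 * bgr[i][o];
    }
    logw[2 * noff] = std::log(absent_prior);

    double mx = logw[0];
    for (size_t t = 1; t < logw.size(); ++t) if (logw[t] > mx) mx = logw[t];
    double total = 0.0;
    for (size_t t = 0; t < logw.size(); ++t) { logw[t] = std::exp(logw[t] - mx); total += logw[t]; }

    double u = unif_rand() * total;
    int pick = (int)logw.size() - 1;
    double acc = 0.0;
    for (size_t t = 0; t < logw.size(); ++t) {
      acc += logw[t];
      if (u <= acc) { pick = (int)t; break; }
    }

    if (pick < 2 * noff) {
      int s = pick >= noff ? 1 : 0;
      int o = pick % noff;
      off[i] = o; str[i] = s;
      for (int j = 0; j < W; ++j) counts[j][site_base(i, o, s, j)] += 1.0;
      ++n_assigned;
    }

    // phase-shift move once per sweep: propose moving the whole alignment
    // by a small delta, sampled by complete-data score
    if ((it + 1) % n == 0 && n_assigned > 0) {
      const int dmax = W / 3;
      std::vector<int> deltas;
      std::vector<double> sc;
      for (int delta = -dmax; delta <= dmax; ++delta) {
        bool valid;
        double s = shifted_score(delta, valid);
        if (valid) { deltas.push_back(delta); sc.push_back(s); }
      }
      if (deltas.size() > 1) {
        double mx2 = sc[0];
        for (size_t t = 1; t < sc.size(); ++t) if (sc[t] > mx2) mx2 = sc[t];
        double tot2 = 0.0;
        for (size_t t = 0; t < sc.size(); ++t) { sc[t] = std::exp(sc[t] - mx2); tot2 += sc[t]; }
        double u2 = unif_rand() * tot2, acc2 = 0.0;
        int chosen = 0;
        for (size_t t = 0; t < sc.size(); ++t) {
          acc2 += sc[t];
          if (u2 <= acc2) { chosen = deltas[t]; break; }
        }
        if (chosen != 0) {
          for (int i2 = 0; i2 < n; ++i2) {
            if (off[i2] < 0) continue;
            off[i2] += (str[i2] == 0 ? chosen : -chosen);
          }
          for (int j = 0; j < W; ++j)
            for (int b = 0; b < 4; ++b) counts[j][b] = 0.0;
          for (int i2 = 0; i2 < n; ++i2) {
            if (off[i2] < 0) continue;
            for (int j = 0; j < W; ++j)
              counts[j][site_base(i2, off[i2], str[i2], j)] += 1.0;
          }
        }
      }
    }
  }

  return List::create(_["offset"] = IntegerVector(off.begin(), off.end()),
                      _["strand"] = IntegerVector(str.begin(), str.end()));
}
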