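#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Median of a vector (destructive); matches stats::median for even n.
static double med_destructive(std::vector<double> &v) {
    const size_t n = v.size();
    if (n == 0) return NA_REAL;
    const size_t k = n / 2;
    std::nth_element(v.begin(), v.begin() + k, v.end());
    double hi = v[k];
    if (n % 2 == 1) return hi;
    double lo = *std::max_element(v.begin(), v.begin() + k);
    return (lo + hi) / 2.0;
}

// add `a` over the circular interval [s, s+len-1] (0-based) of a
// difference array; cumulative summing later yields the rectangle
static void add_rect(std::vector<double> &diff, int n, int s, int len,
                     double a) {
    s %= n; if (s < 0) s += n;
    int e = s + len - 1;
    if (e < n) {
        diff[s] += a;
        if (e + 1 < n) diff[e + 1] -= a;
    } else {                 // wraps: [s, n-1] and [0, e-n]
        diff[s] += a;
        diff[0] += a;
        diff[e - n + 1] -= a;
    }
}

// High-frequency reconstruction of a circular signal via the stationary
// (a-trous) Haar transform.  Forward step t (dilation h = 2^(t-1)):
//   s_t[i] = (s_{t-1}[i] + s_{t-1}[i+h]) / 2
//   w_t[i] = (s_{t-1}[i] - s_{t-1}[i+h]) / 2
// Each detail level is hard-thresholded at lambda_j = C * sigma_j *
// sqrt(2 log n_j), sigma_j = median(|w_j|)/0.6745 (|w| <= lambda -> 0).
// The shift-corrected (branch-averaged) a-trous inverse with the coarsest
// scaling set to zero is then applied.  A single surviving coefficient
// w_t[i] contributes exactly +w 2^-t over the circular block
// [i, i+h-1] and -w 2^-t over [i+h, i+2h-1], so the inverse is
// accumulated sparsely from the survivors and materialized with one
// cumulative sum -- O(n log n) forward, O(survivors + n) inverse.
//
// [[Rcpp::export]]
NumericVector cpp_swt_yhigh(NumericVector x, int nlevels, double C) {
    const int n = x.size();
    if (n < 2 || (n & (n - 1)) != 0)
        stop("signal length must be a power of two");
    if (nlevels < 1 || (1 << nlevels) > n)
        stop("too many decomposition levels for this signal length");

    std::vector<double> s(x.begin(), x.end());
    std::vector<double> scratch(n), head;
    std::vector<double> diff(n, 0.0);
    NumericVector lambdas(nlevels);
    const double root2logn = std::sqrt(2.0 * std::log((double)n));

    std::vector<double> absw(n);
    for (int t = 0; t < nlevels; ++t) {
        const int h = 1 << t;
        // one pass: detail into scratch, scaling updated in place (the
        // head h values are saved because wrapped reads need old ones)
        head.assign(s.begin(), s.begin() + h);
        for (int i = 0; i < n; ++i) {
            const int j = i + h;
            const double b = (j >= n) ? head[j - n] : s[j];
            const double a = s[i];
            const double w = (a - b) / 2.0;
            scratch[i] = w;
            absw[i] = std::fabs(w);
            s[i] = (a + b) / 2.0;
        }
        const double sigma = med_destructive(absw) / 0.6745;
        const double lam = C * sigma * root2logn;
        lambdas[t] = lam;
        const double scale = 1.0 / (double)(2 * h);   // 2^-t
        for (int i = 0; i < n; ++i) {
            if (std::fabs(scratch[i]) > lam) {
                add_rect(diff, n, i, h, scratch[i] * scale);
                add_rect(diff, n, i + h, h, -scratch[i] * scale);
            }
        }
    }

    NumericVector out(n);
    double acc = 0.0, amax = 0.0;
    for (int i = 0; i < n; ++i) {
        acc += diff[i];
        out[i] = acc;
        const double a = std::fabs(acc);
        if (a > amax) amax = a;
    }
    // snap accumulated rounding residue to exact zero: true contributions
    // are >= lambda * 2^-nlevels, many orders above this tolerance
    const double tol = 1e-9 * amax;
    for (int i = 0; i < n; ++i)
        if (std::fabs(out[i]) < tol) out[i] = 0.0;
    out.attr("lambda") = lambdas;
    return out;
}

// Maximal runs of nonzero, same-signed values that do not cross a
// chromosome change.  Returns 1-based start/end (concatenated index),
// sign, value sum and maximum per-position support of each run.
//
// [[Rcpp::export]]
DataFrame cpp_extract_runs(NumericVector v, IntegerVector support,
                           IntegerVector chrom) {
    const int n = v.size();
    if (support.size() != n || chrom.size() != n)
        stop("length mismatch in cpp_extract_runs");
    std::vector<int> start, end, sgn, chr, msup;
    std::vector<double> score;
    int i = 0;
    while (i < n) {
        if (v[i] == 0.0) { ++i; continue; }
        const int s0 = (v[i] > 0) ? 1 : -1;
        const int c0 = chrom[i];
        int j = i;
        double acc = 0.0; int ms = 0;
        while (j < n && v[j] != 0.0 && ((v[j] > 0) ? 1 : -1) == s0 &&
               chrom[j] == c0) {
            acc += v[j];
            if (support[j] > ms) ms = support[j];
            ++j;
        }
        start.push_back(i + 1); end.push_back(j);
        sgn.push_back(s0); chr.push_back(c0);
        score.push_back(acc); msup.push_back(ms);
        i = j;
    }
    return DataFrame::create(_["start"] = start, _["end"] = end,
                             _["sign"] = sgn, _["chrom"] = chr,
                             _["score"] = score, _["support"] = msup);
}

// Maximal nonzero runs (sign may vary inside), split at chromosome
// changes; 1-based coordinates.
//
// [[Rcpp::export]]
DataFrame cpp_nonzero_runs(NumericVector v, IntegerVector chrom) {
    const int n = v.size();
    std::vector<int> start, end, chr;
    int i = 0;
    while (i < n) {
        if (v[i] == 0.0) { ++i; continue; }
        const int c0 = chrom[i];
        int j = i;
        while (j < n && v[j] != 0.0 && chrom[j] == c0) ++j;
        start.push_back(i + 1); end.push_back(j); chr.push_back(c0);
        i = j;
    }
    return DataFrame::create(_["start"] = start, _["end"] = end,
                             _["chrom"] = chr);
}

struct RunRec {
    int start, end, sign, chrom, support, nRuns;
    double score;
};

// streaming state for one (chrom, sign) run stream: groups close at
// gaps > dBins, subgroups at gaps > rBins; each group emits its
// max-|score| subgroup (ties leftmost, i.e. only a strictly greater
// |score| displaces the incumbent).
struct ClusterStream {
    bool active;
    int lastEnd;
    RunRec cur, best;
    ClusterStream() : active(false), lastEnd(0) {}

    void flushGroup(std::vector<RunRec> &out) {
        if (!active) return;
        if (std::fabs(cur.score) > std::fabs(best.score) ||
            best.nRuns == 0)
            best = cur;
        out.push_back(best);
        active = false;
    }
    void add(const RunRec &r, int dBins, int rBins,
             std::vector<RunRec> &out) {
        if (active && r.start - lastEnd - 1 > dBins)
            flushGroup(out);
        if (!active) {
            cur = r; best = r; best.nRuns = 0;   // nRuns 0 = no incumbent
            active = true;
        } else if (r.start - lastEnd - 1 > rBins) {
            // close the current subgroup, open a new one
            if (std::fabs(cur.score) > std::fabs(best.score) ||
                best.nRuns == 0)
                best = cur;
            cur = r;
        } else {
            cur.end = r.end;
            cur.score += r.score;
            if (r.support > cur.support) cur.support = r.support;
            cur.nRuns += 1;
        }
        lastEnd = r.end;
    }
};

// Runs must be sorted by start, chromosome blocks contiguous (as
// extraction guarantees); one pass, no copies.
static void cluster_all(const std::vector<RunRec> &runs, int dBins,
                        int rBins, std::vector<RunRec> &out) {
    ClusterStream pos, neg;
    int curChrom = 0;
    for (size_t i = 0; i < runs.size(); ++i) {
        if (runs[i].chrom != curChrom) {
            pos.flushGroup(out); neg.flushGroup(out);
            curChrom = runs[i].chrom;
        }
        if (runs[i].sign > 0) pos.add(runs[i], dBins, rBins, out);
        else neg.add(runs[i], dBins, rBins, out);
    }
    pos.flushGroup(out); neg.flushGroup(out);
}

// [[Rcpp::export]]
DataFrame cpp_cluster_runs(IntegerVector start, IntegerVector end,
                           IntegerVector sign, IntegerVector chrom,
                           NumericVector score, IntegerVector support,
                           int dBins, int rBins) {
    std::vector<RunRec> runs(start.size());
    for (int i = 0; i < start.size(); ++i) {
        runs[i].start = start[i]; runs[i].end = end[i];
        runs[i].sign = sign[i]; runs[i].chrom = chrom[i];
        runs[i].score = score[i]; runs[i].support = support[i];
        runs[i].nRuns = 1;
    }
    std::vector<RunRec> out;
    cluster_all(runs, dBins, rBins, out);
    const int m = out.size();
    IntegerVector st(m), en(m), sg(m), ch(m), su(m), nr(m);
    NumericVector sc(m);
    for (int i = 0; i < m; ++i) {
        st[i] = out[i].start; en[i] = out[i].end; sg[i] = out[i].sign;
        ch[i] = out[i].chrom; su[i] = out[i].support;
        nr[i] = out[i].nRuns; sc[i] = out[i].score;
    }
    return DataFrame::create(_["start"] = st, _["end"] = en,
                             _["sign"] = sg, _["chrom"] = ch,
                             _["score"] = sc, _["support"] = su,
                             _["nRuns"] = nr);
}

// place one (patient, chromosome) block of runs uniformly at random
// without mutual overlap.  Runs are placed longest first (rejection
// sampling against an occupancy bitmap); if a run cannot be placed after
// maxTries rejections the whole block falls back to sequential random
// non-overlapping placement.  occ must be all-false over [lo-1, hi-1]
// on entry and is left all-false again by the caller's unmarking.
static bool place_runs(const std::vector<int> &lens, int lo, int hi,
                       int maxTries, std::vector<unsigned char> &occ,
                       std::vector<int> &starts) {
    const double T = hi - lo + 1;
    const size_t k = lens.size();
    starts.assign(k, -1);
    std::vector<size_t> ord(k);
    for (size_t q = 0; q < k; ++q) ord[q] = q;
    std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        return lens[a] > lens[b];
    });
    bool ok = true;
    for (size_t oq = 0; oq < k && ok; ++oq) {
        const size_t q = ord[oq];
        const int len = lens[q];
        bool done = false;
        for (int tr = 0; tr < maxTries && !done; ++tr) {
            int st = lo + (int)std::floor(unif_rand() * (T - len + 1));
            if (st + len - 1 > hi) st = hi - len + 1;
            bool clash = false;
            for (int z = 0; z < len; ++z)
                if (occ[st - 1 + z]) { clash = true; break; }
            if (!clash) {
                for (int z = 0; z < len; ++z) occ[st - 1 + z] = 1;
                starts[q] = st;
                done = true;
            }
        }
        if (!done) ok = false;
    }
    if (!ok) {
        // unmark anything placed so far, then fall back
        for (size_t q = 0; q < k; ++q)
            if (starts[q] >= 0)
                for (int z = 0; z < lens[q]; ++z)
                    occ[starts[q] - 1 + z] = 0;
        int total = 0;
        for (size_t z = 0; z < k; ++z) total += lens[z];
        const int free_sp = (int)T - total;
        std::vector<double> cuts(k);
        for (size_t z = 0; z < k; ++z)
            cuts[z] = unif_rand() * (double)free_sp;
        std::sort(cuts.begin(), cuts.end());
        int pos = lo;
        double used = 0.0;
        for (size_t z = 0; z < k; ++z) {
            pos += (int)std::floor(cuts[z] - used);
            used = cuts[z];
            starts[z] = pos;
            pos += lens[z];
        }
        for (size_t z = 0; z < k; ++z)
            for (int y = 0; y < lens[z]; ++y)
                occ[starts[z] - 1 + y] = 1;
        return false;
    }
    return true;
}

// unmark a block's placements
static void unmark_runs(const std::vector<int> &lens,
                        const std::vector<int> &starts,
                        std::vector<unsigned char> &occ) {
    for (size_t q = 0; q < lens.size(); ++q)
        for (int z = 0; z < lens[q]; ++z)
            occ[starts[q] - 1 + z] = 0;
}

// One permutation of the cohort null: every patient's nonzero runs are
// independently reallocated uniformly within their chromosome's
// concatenated territory (no overlap among one patient's runs; overlap
// across patients allowed), then summed.  Values inside a run are kept
// intact and in order.  Uses R's RNG.  Runs must be ordered by
// (patient, chromosome).
//
// [[Rcpp::export]]
List cpp_permute_sum(int n, IntegerVector runLen, IntegerVector runPat,
                     IntegerVector runChr, IntegerVector runOffset,
                     NumericVector runValues, IntegerVector terrLo,
                     IntegerVector terrHi, int maxTries) {
    NumericVector sum(n);
    IntegerVector support(n);
    const int nrun = runLen.size();
    bool fellBack = false;
    int g = 0;
    std::vector<int> lens, starts;
    std::vector<unsigned char> occ(n, 0);
    while (g < nrun) {
        int h = g;
        const int pat = runPat[g], chr = runChr[g];
        while (h < nrun && runPat[h] == pat && runChr[h] == chr) ++h;
        lens.assign(runLen.begin() + g, runLen.begin() + h);
        if (!place_runs(lens, terrLo[chr - 1], terrHi[chr - 1], maxTries,
                        occ, starts))
            fellBack = true;
        for (int q = g; q < h; ++q) {
            const int st = starts[q - g], len = runLen[q];
            const int off = runOffset[q] - 1;
            for (int z = 0; z < len; ++z) {
                sum[st - 1 + z] += runValues[off + z];
                support[st - 1 + z] += 1;
            }
        }
        unmark_runs(lens, starts, occ);
        g = h;
    }
    if (fellBack)
        Rf_warning("run placement fell back to sequential packing");
    return List::create(_["sum"] = sum, _["support"] = support);
}

// The full permutation null: B independent cohort permutations, each
// summed, run-extracted and clustered with the same dBins/rBins as the
// observed analysis.  Returns one row per random cluster with its
// permutation index.  Runs must be ordered by (patient, chromosome).
//
// [[Rcpp::export]]
DataFrame cpp_build_null(int B, int n, IntegerVector runLen,
                         IntegerVector runPat, IntegerVector runChr,
                         IntegerVector runOffset, NumericVector runValues,
                         IntegerVector terrLo, IntegerVector terrHi,
                         IntegerVector posChrom, int dBins, int rBins,
                         int maxTries) {
    const int nrun = runLen.size();
    std::vector<double> sum(n);
    std::vector<int> support(n);
    std::vector<int> lens, starts;
    std::vector<unsigned char> occ(n, 0);
    std::vector<RunRec> runs, clusters;
    std::vector<int> operm; std::vector<RunRec> oall;
    bool fellBack = false;

    for (int b = 1; b <= B; ++b) {
        int g = 0;
        while (g < nrun) {
            int h = g;
            const int pat = runPat[g], chr = runChr[g];
            while (h < nrun && runPat[h] == pat && runChr[h] == chr) ++h;
            lens.assign(runLen.begin() + g, runLen.begin() + h);
            if (!place_runs(lens, terrLo[chr - 1], terrHi[chr - 1],
                            maxTries, occ, starts))
                fellBack = true;
            for (int q = g; q < h; ++q) {
                const int st = starts[q - g], len = runLen[q];
                const int off = runOffset[q] - 1;
                for (int z = 0; z < len; ++z) {
                    sum[st - 1 + z] += runValues[off + z];
                    support[st - 1 + z] += 1;
                }
            }
            unmark_runs(lens, starts, occ);
            g = h;
        }
        // extract same-sign runs with one pass over the signal
        runs.clear();
        int i = 0;
        while (i < n) {
            if (sum[i] == 0.0) { ++i; continue; }
            const int s0 = (sum[i] > 0) ? 1 : -1;
            const int c0 = posChrom[i];
            RunRec r; r.start = i + 1; r.sign = s0; r.chrom = c0;
            r.score = 0.0; r.support = 0; r.nRuns = 1;
            int q = i;
            while (q < n && sum[q] != 0.0 &&
                   ((sum[q] > 0) ? 1 : -1) == s0 && posChrom[q] == c0) {
                r.score += sum[q];
                if (support[q] > r.support) r.support = support[q];
                ++q;
            }
            r.end = q;
            runs.push_back(r);
            i = q;
        }
        clusters.clear();
        cluster_all(runs, dBins, rBins, clusters);
        for (size_t c = 0; c < clusters.size(); ++c) {
            operm.push_back(b);
            oall.push_back(clusters[c]);
        }
        std::fill(sum.begin(), sum.end(), 0.0);
        std::fill(support.begin(), support.end(), 0);
    }
    if (fellBack)
        Rf_warning("run placement fell back to sequential packing");
    const int m = oall.size();
    IntegerVector perm(m), st(m), en(m), sg(m), su(m);
    NumericVector sc(m);
    for (int i = 0; i < m; ++i) {
        perm[i] = operm[i]; st[i] = oall[i].start; en[i] = oall[i].end;
        sg[i] = oall[i].sign; su[i] = oall[i].support;
        sc[i] = oall[i].score;
    }
    return DataFrame::create(_["perm"] = perm, _["start"] = st,
                             _["end"] = en, _["sign"] = sg,
                             _["score"] = sc, _["support"] = su);
}

// --- fast samplers on R's RNG ------------------------------------------

// Marsaglia-Tsang (2000) gamma generator, shape >= 1
static double gamma_mt(double shape) {
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
        double x, v;
        do { x = norm_rand(); v = 1.0 + c * x; } while (v <= 0.0);
        v = v * v * v;
        const double u = unif_rand();
        if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
        if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
            return d * v;
    }
}

static double gamma_draw(double shape) {
    if (shape >= 1.0) return gamma_mt(shape);
    const double g = gamma_mt(shape + 1.0);
    return g * std::pow(unif_rand(), 1.0 / shape);
}

// Poisson: Knuth product for small means, PTRS transformed rejection
// (Hormann 1993) otherwise
static int pois_draw(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 10.0) {
        const double L = std::exp(-lambda);
        int k = 0;
        double p = 1.0;
        do { ++k; p *= unif_rand(); } while (p > L);
        return k - 1;
    }
    const double b = 0.931 + 2.53 * std::sqrt(lambda);
    const double a = -0.059 + 0.02483 * b;
    const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    const double vr = 0.9277 - 3.6224 / (b - 2.0);
    for (;;) {
        const double u = unif_rand() - 0.5;
        const double v = unif_rand();
        const double us = 0.5 - std::fabs(u);
        const int k = (int)std::floor((2.0 * a / us + b) * u + lambda + 0.43);
        if (us >= 0.07 && v <= vr) return k;
        if (k < 0 || (us < 0.013 && v > us)) continue;
        if (std::log(v) + std::log(inv_alpha) - std::log(a / (us * us) + b)
            <= k * std::log(lambda) - lambda - R::lgammafn(k + 1.0))
            return k;
    }
}

// Negative-binomial counts with per-element mean `mu` and common `size`
// (gamma-Poisson mixture); uses R's RNG, so draws are reproducible under
// set.seed().
//
// [[Rcpp::export]]
NumericVector cpp_rnbinom_mu(NumericVector mu, double size) {
    const int n = mu.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        if (mu[i] <= 0.0) { out[i] = 0.0; continue; }
        const double lam = gamma_draw(size) * (mu[i] / size);
        out[i] = pois_draw(lam);
    }
    return out;
}

// Chromosome-normalized log2 ratio in one pass.  tcChrom/ncChrom give
// each bin's chromosome totals (pre-expanded); bins with a zero count on
// either side, or on a zero-total chromosome, are invalid (ratio 0).
//
// [[Rcpp::export]]
List cpp_log2_ratio(NumericVector tumor, NumericVector normal,
                    NumericVector tcChrom, NumericVector ncChrom) {
    const int n = tumor.size();
    NumericVector ratio(n);
    LogicalVector valid(n);
    const double l2 = std::log(2.0);
    for (int i = 0; i < n; ++i) {
        if (tumor[i] > 0.0 && normal[i] > 0.0 &&
            tcChrom[i] > 0.0 && ncChrom[i] > 0.0) {
            ratio[i] = (std::log(tumor[i] / tcChrom[i]) -
                        std::log(normal[i] / ncChrom[i])) / l2;
            valid[i] = true;
        }
    }
    return List::create(_["ratio"] = ratio, _["valid"] = valid);
}

// Sliding-window winsorization of per-base counts: each position whose
// value exceeds the type-1 empirical `q` quantile (an order statistic) of
// its centered `window`-bp neighborhood is capped at that quantile.
//
// [[Rcpp::export]]
NumericVector cpp_window_winsorize(NumericVector x, int window, double q) {
    const int n = x.size();
    NumericVector out = clone(x);
    if (n == 0) return out;
    const int left = window / 2 - 1, right = window - (window / 2);
    std::vector<double> buf;
    buf.reserve(window);
    for (int i = 0; i < n; ++i) {
        int lo = i - left; if (lo < 0) lo = 0;
        int hi = i + right; if (hi > n - 1) hi = n - 1;
        const int m = hi - lo + 1;
        int k = (int)std::ceil(q * m);          // type-1 quantile
        if (k < 1) k = 1;
        if (k > m) k = m;
        buf.assign(x.begin() + lo, x.begin() + hi + 1);
        std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
        const double thr = buf[k - 1];
        if (x[i] > thr) out[i] = thr;
    }
    return out;
}
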