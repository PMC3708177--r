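#include <Rcpp.h>
using namespace Rcpp;

// Periodic wrap to [-180, 180); floor-based, matching R's %% semantics.
static inline double wrapd(double a) {
    return a - 360.0 * std::floor((a + 180.0) / 360.0);
}

// Sum of negative Gaussian wells in angular distance. Wells with
// non-positive effective depth are abolished (skipped); contributions
// beyond 6 widths (< exp(-18) of the depth) are truncated to zero.
// The R-side energy uses the identical truncation rule.
static double well_energy(const double* x, int d,
                          const NumericMatrix& centers,
                          const NumericVector& depth,
                          const NumericVector& width) {
    double e = 0.0;
    const int nb = centers.nrow();
    for (int b = 0; b < nb; ++b) {
        const double D = depth[b];
        if (D <= 0.0) continue;
        const double w2 = width[b] * width[b];
        const double lim = 36.0 * w2;
        double s = 0.0;
        bool far = false;
        for (int k = 0; k < d; ++k) {
            const double dd = wrapd(x[k] - centers(b, k));
            s += dd * dd;
            if (s > lim) { far = true; break; }
        }
        if (!far) e -= D * std::exp(-s / (2.0 * w2));
    }
    return e;
}

// [[Rcpp::export]]
double landscape_energy_cpp(NumericVector x, NumericMatrix centers,
                            NumericVector depth, NumericVector width) {
    return well_energy(REAL(x), x.size(), centers, depth, width);
}

// Replica-exchange Metropolis sampler on a periodic torsion torus.
//
// Per sweep (= one time unit) each bath performs one single-coordinate
// Metropolis update per dimension, plus, with probability jump_prob, one
// symmetric whole-torus uniform jump proposal. Every swap_every sweeps one
// randomly chosen parity of adjacent-bath pairs is exchanged with the
// Metropolis criterion min(1, exp((beta_i - beta_j)(E_i - E_j))).
// Snapshots of the baths listed in `keep` (1-based) are stored every
// snap_every sweeps once t > equil. Uses R's RNG throughout.
// [[Rcpp::export]]
List pt_run_cpp(NumericMatrix centers, NumericVector depth, NumericVector width,
                NumericVector temps, double kB,
                int total, int swap_every, int snap_every, int equil,
                double step, double jump_prob,
                NumericVector init, IntegerVector keep) {
    const int nb = temps.size();
    const int d = init.size();
    const int nkeep = keep.size();
    const int nframes = (total - equil) / snap_every;

    NumericMatrix S(nb, d);
    NumericVector E(nb);
    std::vector<double> beta(nb);
    for (int i = 0; i < nb; ++i) {
        for (int k = 0; k < d; ++k) S(i, k) = init[k];
        beta[i] = 1.0 / (kB * temps[i]);
    }
    std::vector<double> row(d);
    for (int i = 0; i < nb; ++i) {
        for (int k = 0; k < d; ++k) row[k] = S(i, k);
        E[i] = well_energy(row.data(), d, centers, depth, width);
        if (!R_finite(E[i])) stop("non-finite energy at initial state");
    }

    List frames(nkeep);
    std::vector<double*> fptr(nkeep);
    for (int j = 0; j < nkeep; ++j) {
        NumericMatrix F(nframes, d);
        frames[j] = F;
        fptr[j] = REAL(F);
    }

    IntegerVector attempts(nb > 1 ? nb - 1 : 0);
    IntegerVector accepts(nb > 1 ? nb - 1 : 0);
    std::vector<double> prop(d);

    for (int t = 1; t <= total; ++t) {
        for (int i = 0; i < nb; ++i) {
            const double bi = beta[i];
            for (int k = 0; k < d; ++k) prop[k] = S(i, k);
            // single-coordinate Metropolis updates
            for (int k = 0; k < d; ++k) {
                const double xold = prop[k];
                prop[k] = wrapd(xold + (2.0 * unif_rand() - 1.0) * step);
                const double enew = well_energy(prop.data(), d, centers, depth, width);
                const double de = enew - E[i];
                if (de <= 0.0 || unif_rand() < std::exp(-bi * de)) {
                    E[i] = enew;
                    S(i, k) = prop[k];
                } else {
                    prop[k] = xold;
                }
            }
            // occasional whole-torus jump (symmetric uniform proposal)
            if (jump_prob > 0.0 && unif_rand() < jump_prob) {
                for (int k = 0; k < d; ++k)
                    prop[k] = 360.0 * unif_rand() - 180.0;
                const double enew = well_energy(prop.data(), d, centers, depth, width);
                const double de = enew - E[i];
                if (de <= 0.0 || unif_rand() < std::exp(-bi * de)) {
                    E[i] = enew;
                    for (int k = 0; k < d; ++k) S(i, k) = prop[k];
                }
            }
        }
        if (swap_every > 0 && nb > 1 && t % swap_every == 0) {
            const int parity = (unif_rand() < 0.5) ? 0 : 1;
            for (int i = parity; i + 1 < nb; i += 2) {
                attempts[i] += 1;
                const double arg = (beta[i] - beta[i + 1]) * (E[i] - E[i + 1]);
                if (arg >= 0.0 || unif_rand() < std::exp(arg)) {
                    accepts[i] += 1;
                    for (int k = 0; k < d; ++k) {
                        const double tmp = S(i, k);
                        S(i, k) = S(i + 1, k);
                        S(i + 1, k) = tmp;
                    }
                    const double te = E[i]; E[i] = E[i + 1]; E[i + 1] = te;
                }
            }
        }
        if (t > equil && (t - equil) % snap_every == 0) {
            const int r = (t - equil) / snap_every - 1;
            for (int j = 0; j < nkeep; ++j) {
                const int bi = keep[j] - 1;
                for (int k = 0; k < d; ++k)
                    fptr[j][r + (R_xlen_t)k * nframes] = S(bi, k);
            }
        }
    }

    return List::create(_["frames"] = frames,
                        _["attempts"] = attempts,
                        _["accepts"] = accepts,
                        _["final_state"] = S,
                        _["final_energy"] = E,
                        _["n_frames"] = nframes);
}

// Leader (first-fit) clustering. Frames are scanned in input order; a frame
// joins the first existing center (in creation order) within `cutoff`,
// otherwise it founds a new center. Distance is sqrt(sum(delta^2) / denom)
// with periodic wrapping when `angular` (denom = n dimensions for angular
// RMS, n atoms for Cartesian RMSD over flattened xyz rows).
// [[Rcpp::export]]
List leader_cluster_cpp(NumericMatrix X, double cutoff, double denom, bool angular) {
    const R_xlen_t n = X.nrow();
    const int d = X.ncol();
    const double lim = cutoff * cutoff * denom;
    IntegerVector assign_(n);
    std::vector<R_xlen_t> centers;
    centers.reserve(64);
    const double* xp = REAL(X);
    for (R_xlen_t i = 0; i < n; ++i) {
        int hit = -1;
        for (size_t c = 0; c < centers.size(); ++c) {
            const R_xlen_t j = centers[c];
            double s = 0.0;
            for (int k = 0; k < d; ++k) {
                double dd = xp[i + (R_xlen_t)k * n] - xp[j + (R_xlen_t)k * n];
                if (angular) dd = wrapd(dd);
                s += dd * dd;
                if (s > lim) break;
            }
            if (s <= lim) { hit = (int)c; break; }
        }
        if (hit < 0) {
            centers.push_back(i);
            hit = (int)centers.size() - 1;
        }
        assign_[i] = hit + 1;
    }
    IntegerVector cen(centers.size());
    for (size_t c = 0; c < centers.size(); ++c) cen[c] = (int)(centers[c] + 1);
    return List::create(_["assignment"] = assign_, _["centers"] = cen);
}
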