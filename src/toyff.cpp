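// Coarse-grained peptide force field and overdamped Langevin propagator.
//
// Beads: one backbone bead per residue (at Calpha) and one side-chain bead
// per non-glycine residue (at Cbeta); terminal backbone beads carry the
// formal +1/-1 charges. Terms:
//   bonded      harmonic bonds and angles keeping chains near-extended
//   elec        screened Coulomb, 332.0637 q_i q_j exp(-r/lD) / (eps_r r)
//   hbond       Gaussian well between backbone beads of different peptides
//               (surrogate for backbone hydrogen bonding)
//   packing     Gaussian well between side-chain beads of different
//               peptides; side chains that mutually face each other
//               (interdigitating across a zipper interface) and carry the
//               same residue index gain an extra homotypic in-register
//               stacking bonus. The facing gate uses the CA->CB bond
//               direction; its orientational derivative is neglected in
//               the gradient (forces are approximate for this factor).
//   repulsion   soft half-harmonic excluded volume between peptides
//   solvation   exposure penalty from a smooth coordination deficit
// Nonbonded terms act only between beads of different peptides; intrachain
// structure is maintained by the bonded terms (and, in HREMD, the
// reference restraint).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct FFParams {
  double eps_r, debye_len, coulomb_k;
  double e_hb, hb_r0, hb_w;
  double e_pack, e_same, pack_r0, pack_w;
  double k_rep, rep_sigma;
  double solv_gamma, solv_c0, solv_rs;
  double cutoff;
  double w_bonded, w_elec, w_hbond, w_pack, w_solv;
};

static FFParams parse_params(const List& p) {
  FFParams f;
  f.eps_r = as<double>(p["eps_r"]);
  f.debye_len = as<double>(p["debye_len"]);
  f.coulomb_k = 332.0637;
  f.e_hb = as<double>(p["e_hb"]);
  f.hb_r0 = as<double>(p["hb_r0"]);
  f.hb_w = as<double>(p["hb_w"]);
  f.e_pack = as<double>(p["e_pack"]);
  f.e_same = as<double>(p["e_same"]);
  f.pack_r0 = as<double>(p["pack_r0"]);
  f.pack_w = as<double>(p["pack_w"]);
  f.k_rep = as<double>(p["k_rep"]);
  f.rep_sigma = as<double>(p["rep_sigma"]);
  f.solv_gamma = as<double>(p["solv_gamma"]);
  f.solv_c0 = as<double>(p["solv_c0"]);
  f.solv_rs = as<double>(p["solv_rs"]);
  f.cutoff = as<double>(p["cutoff"]);
  f.w_bonded = as<double>(p["w_bonded"]);
  f.w_elec = as<double>(p["w_elec"]);
  f.w_hbond = as<double>(p["w_hbond"]);
  f.w_pack = as<double>(p["w_pack"]);
  f.w_solv = as<double>(p["w_solv"]);
  return f;
}

// Core evaluation. terms: bonded, elec, hbond, packing, solvation
// (repulsion is folded into packing for reporting symmetry of the zipper
// term? no -- keep it separate). Order:
// 0 bonded, 1 packing, 2 elec, 3 hbond, 4 solvation, 5 repulsion
static void eval_ff(const arma::mat& x, const arma::ivec& pep,
                    const arma::ivec& type, const arma::ivec& resid,
                    const arma::ivec& partner, const arma::vec& charge,
                    const arma::mat& bonds,
                    const arma::mat& angles, const FFParams& f,
                    bool want_grad, arma::vec& terms, arma::mat& grad,
                    arma::vec& per_pep, int npep) {
  const arma::uword n = x.n_rows;
  terms.zeros(6);
  if (want_grad) grad.zeros(n, 3);
  per_pep.zeros(npep);

  // bonds: columns i, j, r0, k (0-based indices)
  for (arma::uword b = 0; b < bonds.n_rows; ++b) {
    const int i = (int)bonds(b, 0), j = (int)bonds(b, 1);
    const double r0 = bonds(b, 2), k = bonds(b, 3);
    arma::rowvec d = x.row(i) - x.row(j);
    const double r = arma::norm(d);
    const double e = 0.5 * k * (r - r0) * (r - r0) * f.w_bonded;
    terms(0) += e;
    per_pep(pep(i)) += 0.5 * e;
    per_pep(pep(j)) += 0.5 * e;
    if (want_grad && r > 1e-12) {
      arma::rowvec g = f.w_bonded * k * (r - r0) * d / r;
      grad.row(i) += g;
      grad.row(j) -= g;
    }
  }
  // angles: columns i, j, k, theta0, kang
  for (arma::uword a = 0; a < angles.n_rows; ++a) {
    const int i = (int)angles(a, 0), j = (int)angles(a, 1), k = (int)angles(a, 2);
    const double th0 = angles(a, 3), ka = angles(a, 4);
    arma::rowvec rij = x.row(i) - x.row(j);
    arma::rowvec rkj = x.row(k) - x.row(j);
    const double nij = arma::norm(rij), nkj = arma::norm(rkj);
    if (nij < 1e-12 || nkj < 1e-12) continue;
    double cs = arma::dot(rij, rkj) / (nij * nkj);
    cs = std::max(-1.0, std::min(1.0, cs));
    const double th = std::acos(cs);
    const double e = 0.5 * ka * (th - th0) * (th - th0) * f.w_bonded;
    terms(0) += e;
    per_pep(pep(j)) += e;
    if (want_grad) {
      const double sn = std::sqrt(std::max(1e-12, 1.0 - cs * cs));
      const double coef = f.w_bonded * ka * (th - th0) * (-1.0 / sn);
      arma::rowvec di = (rkj / (nij * nkj)) - cs * rij / (nij * nij);
      arma::rowvec dk = (rij / (nij * nkj)) - cs * rkj / (nkj * nkj);
      grad.row(i) += coef * di;
      grad.row(k) += coef * dk;
      grad.row(j) -= coef * (di + dk);
    }
  }

  // pairwise nonbonded (different peptides only) + coordination for solvation
  arma::vec coordn(n, arma::fill::zeros);
  arma::mat coordgrad_acc; // accumulated later
  const double rs2inv = 1.0 / (2.0 * f.solv_rs * f.solv_rs);
  const bool do_solv = f.w_solv != 0.0 && f.solv_gamma != 0.0;

  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      if (pep(i) == pep(j)) continue;
      arma::rowvec d = x.row(i) - x.row(j);
      const double r = arma::norm(d);
      if (r > f.cutoff || r < 1e-12) continue;
      arma::rowvec u = d / r;
      double dEdr = 0.0;

      // electrostatics
      if (charge(i) != 0.0 && charge(j) != 0.0 && f.w_elec != 0.0) {
        const double screen = std::isfinite(f.debye_len) ? std::exp(-r / f.debye_len) : 1.0;
        const double e = f.w_elec * f.coulomb_k * charge(i) * charge(j) * screen / (f.eps_r * r);
        terms(2) += e;
        per_pep(pep(i)) += 0.5 * e;
        per_pep(pep(j)) += 0.5 * e;
        if (want_grad) {
          double de = -e / r;
          if (std::isfinite(f.debye_len)) de += -e / f.debye_len;
          dEdr += de;
        }
      }
      // backbone hydrogen-bond surrogate
      if (type(i) == 0 && type(j) == 0 && f.w_hbond != 0.0 && f.e_hb != 0.0) {
        const double dv = (r - f.hb_r0) / f.hb_w;
        const double e = -f.w_hbond * f.e_hb * std::exp(-0.5 * dv * dv);
        terms(3) += e;
        per_pep(pep(i)) += 0.5 * e;
        per_pep(pep(j)) += 0.5 * e;
        if (want_grad) dEdr += -e * dv / f.hb_w;
      }
      // side-chain packing (+ facing-gated in-register homotypic bonus)
      if (type(i) == 1 && type(j) == 1 && f.w_pack != 0.0) {
        double depth = f.e_pack;
        if (resid(i) == resid(j) && f.e_same != 0.0 && partner(i) >= 0 &&
            partner(j) >= 0) {
          arma::rowvec vi = x.row(i) - x.row(partner(i));
          arma::rowvec vj = x.row(j) - x.row(partner(j));
          const double ni_ = arma::norm(vi), nj_ = arma::norm(vj);
          if (ni_ > 1e-9 && nj_ > 1e-9) {
            const double si = std::max(0.0, -arma::dot(u, vi) / ni_);
            const double sj = std::max(0.0, arma::dot(u, vj) / nj_);
            depth += f.e_same * si * sj;
          }
        }
        if (depth != 0.0) {
          const double dv = (r - f.pack_r0) / f.pack_w;
          const double e = -f.w_pack * depth * std::exp(-0.5 * dv * dv);
          terms(1) += e;
          per_pep(pep(i)) += 0.5 * e;
          per_pep(pep(j)) += 0.5 * e;
          if (want_grad) dEdr += -e * dv / f.pack_w;
        }
      }
      // soft excluded volume
      if (r < f.rep_sigma && f.k_rep != 0.0) {
        const double e = 0.5 * f.k_rep * (f.rep_sigma - r) * (f.rep_sigma - r);
        terms(5) += e;
        per_pep(pep(i)) += 0.5 * e;
        per_pep(pep(j)) += 0.5 * e;
        if (want_grad) dEdr += -f.k_rep * (f.rep_sigma - r);
      }
      if (want_grad && dEdr != 0.0) {
        grad.row(i) += dEdr * u;
        grad.row(j) -= dEdr * u;
      }
      if (do_solv) {
        const double w = std::exp(-r * r * rs2inv);
        coordn(i) += w;
        coordn(j) += w;
      }
    }
  }

  if (do_solv) {
    // E = gamma * sum_i softplus(c0 - c_i), softplus for smoothness
    for (arma::uword i = 0; i < n; ++i) {
      const double zv = f.solv_c0 - coordn(i);
      const double sp = (zv > 30) ? zv : std::log1p(std::exp(zv));
      const double e = f.w_solv * f.solv_gamma * sp;
      terms(4) += e;
      per_pep(pep(i)) += e;
    }
    if (want_grad) {
      for (arma::uword i = 0; i + 1 < n; ++i) {
        for (arma::uword j = i + 1; j < n; ++j) {
          if (pep(i) == pep(j)) continue;
          arma::rowvec d = x.row(i) - x.row(j);
          const double r = arma::norm(d);
          if (r > f.cutoff || r < 1e-12) continue;
          const double w = std::exp(-r * r * rs2inv);
          const double zi = f.solv_c0 - coordn(i);
          const double zj = f.solv_c0 - coordn(j);
          const double si = 1.0 / (1.0 + std::exp(-zi));
          const double sj = 1.0 / (1.0 + std::exp(-zj));
          // dE/dr = gamma * (-(si + sj)) * dw/dr
          const double dwdr = -2.0 * r * rs2inv * w;
          const double dEdr = -f.w_solv * f.solv_gamma * (si + sj) * dwdr;
          arma::rowvec g = dEdr * d / r;
          grad.row(i) += g;
          grad.row(j) -= g;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List toy_energy_cpp(const arma::mat& coords, const arma::ivec& pep,
                    const arma::ivec& type, const arma::ivec& resid,
                    const arma::ivec& partner, const arma::vec& charge,
                    const arma::mat& bonds,
                    const arma::mat& angles, const List& params,
                    bool want_grad) {
  FFParams f = parse_params(params);
  const int npep = pep.max() + 1;
  arma::vec terms;
  arma::mat grad;
  arma::vec per_pep;
  eval_ff(coords, pep, type, resid, partner, charge, bonds, angles, f, want_grad,
          terms, grad, per_pep, npep);
  CharacterVector nm = CharacterVector::create(
      "bonded", "packing", "electrostatic", "hbond", "solvation", "repulsion");
  NumericVector tv(terms.begin(), terms.end());
  tv.attr("names") = nm;
  List out = List::create(
      Named("total") = arma::accu(terms),
      Named("terms") = tv,
      Named("per_peptide") = NumericVector(per_pep.begin(), per_pep.end()));
  if (want_grad) out["gradient"] = wrap(grad);
  return out;
}

// Proper (det +1) Kabsch rotation+translation of ref onto tgt.
static void kabsch_fit(const arma::mat& ref, const arma::mat& tgt,
                       arma::mat& fitted) {
  arma::rowvec cr = arma::mean(ref, 0), ct = arma::mean(tgt, 0);
  arma::mat r0 = ref.each_row() - cr, t0 = tgt.each_row() - ct;
  arma::mat h = r0.t() * t0;
  arma::mat u, v;
  arma::vec s;
  arma::svd(u, s, v, h);
  arma::mat d = arma::eye(3, 3);
  d(2, 2) = arma::det(v * u.t()) < 0 ? -1.0 : 1.0;
  arma::mat rot = v * d * u.t();
  arma::mat moved = r0 * rot.t();
  fitted = moved.each_row() + ct;
}

// Sum over peptides of (1/2)|x - T(ref)|^2 with T the optimal rigid fit of
// the reference onto the peptide (restraint energy per unit lambda).
// [[Rcpp::export]]
double restraint_sum_cpp(const arma::mat& coords, const arma::ivec& pep,
                         const arma::mat& ref, int npep) {
  const int nb = ref.n_rows;
  double total = 0.0;
  arma::mat fitted;
  for (int p = 0; p < npep; ++p) {
    arma::mat tgt(nb, 3);
    int k = 0;
    for (arma::uword i = 0; i < coords.n_rows; ++i)
      if (pep(i) == p) tgt.row(k++) = coords.row(i);
    kabsch_fit(ref, tgt, fitted);
    total += 0.5 * arma::accu(arma::square(tgt - fitted));
  }
  return total;
}

// Overdamped Langevin propagation with the toy force field, a harmonic
// reference restraint of strength lambda and half-harmonic spherical
// confinement on peptide centroids. Uses R's RNG (seed with set.seed).
// [[Rcpp::export]]
List langevin_segment_cpp(const arma::mat& coords0, const arma::ivec& pep,
                          const arma::ivec& type, const arma::ivec& resid,
                          const arma::ivec& partner, const arma::vec& charge,
                          const arma::mat& bonds,
                          const arma::mat& angles, const List& params,
                          const arma::mat& ref, double lambda, int n_steps,
                          double dt, double temperature, double friction,
                          double conf_radius, double conf_k) {
  FFParams f = parse_params(params);
  const arma::uword n = coords0.n_rows;
  const int npep = pep.max() + 1;
  const int nb = ref.n_rows;
  arma::mat x = coords0;
  arma::vec terms;
  arma::mat grad;
  arma::vec per_pep;
  const double kB = 0.0019872041;
  const double mob = dt / friction;
  const double sig = std::sqrt(2.0 * kB * temperature * dt / friction);

  // per-peptide bead index lists
  std::vector<std::vector<int>> members(npep);
  for (arma::uword i = 0; i < n; ++i) members[pep(i)].push_back((int)i);

  arma::mat fitted;
  for (int step = 0; step < n_steps; ++step) {
    eval_ff(x, pep, type, resid, partner, charge, bonds, angles, f, true, terms, grad,
            per_pep, npep);
    // restraint forces: lambda * (x - T(ref))
    if (lambda > 0.0) {
      for (int p = 0; p < npep; ++p) {
        arma::mat tgt(nb, 3);
        for (int k = 0; k < nb; ++k) tgt.row(k) = x.row(members[p][k]);
        kabsch_fit(ref, tgt, fitted);
        for (int k = 0; k < nb; ++k)
          grad.row(members[p][k]) += lambda * (tgt.row(k) - fitted.row(k));
      }
    }
    // confinement on centroids
    if (std::isfinite(conf_radius)) {
      for (int p = 0; p < npep; ++p) {
        arma::rowvec cen(3, arma::fill::zeros);
        for (int k : members[p]) cen += x.row(k);
        cen /= (double)members[p].size();
        const double d = arma::norm(cen);
        if (d > conf_radius) {
          arma::rowvec g = conf_k * (d - conf_radius) * cen / d /
                           (double)members[p].size();
          for (int k : members[p]) grad.row(k) += g;
        }
      }
    }
    for (arma::uword i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        x(i, c) += -mob * grad(i, c) + sig * R::norm_rand();
  }

  eval_ff(x, pep, type, resid, partner, charge, bonds, angles, f, false, terms, grad,
          per_pep, npep);
  return List::create(
      Named("coords") = wrap(x),
      Named("potential") = arma::accu(terms),
      Named("restraint_sum") = restraint_sum_cpp(x, pep, ref, npep));
}
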