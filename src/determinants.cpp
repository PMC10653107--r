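// Determinant algebra for RAS configuration interaction.
//
// Conventions (fixed once, used everywhere):
//  * n_spin = 2*n_orb spin orbitals; index p in 0..n_spin-1 is bit p of a
//    64-bit occupation word.  p < n_orb is the alpha spin orbital of spatial
//    orbital p; p >= n_orb is the beta spin orbital of spatial p - n_orb.
//  * |D> = a+_{p1} a+_{p2} ... a+_{pN} |vac> with p1 < p2 < ... < pN, so the
//    sign of a_p acting on |D> is (-1)^(number of occupied bits below p).
//  * Determinant words are exchanged with R as doubles; n_spin <= 52 keeps
//    them exact.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

typedef std::unordered_map<uint64_t, int> DetMap;

static inline uint64_t as_word(double d) {
  return static_cast<uint64_t>(d + 0.5);
}

static inline int bits_below(uint64_t w, int p) {
  if (p == 0) return 0;
  return __builtin_popcountll(w & ((1ULL << p) - 1ULL));
}

// sign of a_p |w>; sets *ok = false when p is empty
static inline int annihilate(uint64_t &w, int p, bool &ok) {
  if (!(w >> p & 1ULL)) { ok = false; return 0; }
  int s = (bits_below(w, p) % 2) ? -1 : 1;
  w &= ~(1ULL << p);
  return s;
}

// sign of a+_p |w>; sets *ok = false when p is occupied
static inline int create(uint64_t &w, int p, bool &ok) {
  if (w >> p & 1ULL) { ok = false; return 0; }
  int s = (bits_below(w, p) % 2) ? -1 : 1;
  w |= (1ULL << p);
  return s;
}

static DetMap build_map(const NumericVector &dets) {
  DetMap m;
  m.reserve(dets.size() * 2);
  for (int i = 0; i < dets.size(); ++i) m[as_word(dets[i])] = i;
  return m;
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(NumericVector dets) {
  IntegerVector out(dets.size());
  for (int i = 0; i < dets.size(); ++i)
    out[i] = __builtin_popcountll(as_word(dets[i]));
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_det_bits(NumericVector dets, int n_spin) {
  IntegerMatrix out(dets.size(), n_spin);
  for (int i = 0; i < dets.size(); ++i) {
    uint64_t w = as_word(dets[i]);
    for (int p = 0; p < n_spin; ++p) out(i, p) = (w >> p) & 1ULL;
  }
  return out;
}

// Apply a+_{create} a_{annihilate}; returns c(new_det, sign), sign 0 == null.
// Indices are 1-based spin orbitals.
// [[Rcpp::export]]
NumericVector cpp_excite(double det, int create1, int annihilate1) {
  uint64_t w = as_word(det);
  bool ok = true;
  int s1 = annihilate(w, annihilate1 - 1, ok);
  if (!ok) return NumericVector::create(0.0, 0.0);
  int s2 = create(w, create1 - 1, ok);
  if (!ok) return NumericVector::create(0.0, 0.0);
  return NumericVector::create(static_cast<double>(w),
                               static_cast<double>(s1 * s2));
}

struct TripletSink {
  std::vector<int> i, j;
  std::vector<double> re, im;
  void push(int row, int col, double xr, double xi) {
    if (std::fabs(xr) < 1e-15 && std::fabs(xi) < 1e-15) return;
    i.push_back(row + 1);
    j.push_back(col + 1);
    re.push_back(xr);
    im.push_back(xi);
  }
  List as_list() const {
    return List::create(_["i"] = wrap(i), _["j"] = wrap(j),
                        _["re"] = wrap(re), _["im"] = wrap(im));
  }
};

// Sparse matrix (triplets) of a one-body spin-orbital operator
// sum_{rp} O[r,p] a+_r a_p projected onto the determinant basis.
// [[Rcpp::export]]
List cpp_build_onebody(NumericVector dets, int n_spin, ComplexMatrix O) {
  DetMap map = build_map(dets);
  TripletSink out;
  int nd = dets.size();
  std::vector<int> occ;
  occ.reserve(n_spin);
  for (int J = 0; J < nd; ++J) {
    uint64_t D = as_word(dets[J]);
    occ.clear();
    for (int p = 0; p < n_spin; ++p)
      if (D >> p & 1ULL) occ.push_back(p);
    double dre = 0.0, dim_ = 0.0;
    for (size_t a = 0; a < occ.size(); ++a) {
      int p = occ[a];
      for (int r = 0; r < n_spin; ++r) {
        Rcomplex o = O(r, p);
        if (o.r == 0.0 && o.i == 0.0) continue;
        if (r == p) {
          dre += o.r;
          dim_ += o.i;
        } else if (!(D >> r & 1ULL)) {
          uint64_t w = D;
          bool ok = true;
          int s = annihilate(w, p, ok);
          s *= create(w, r, ok);
          DetMap::const_iterator it = map.find(w);
          if (it == map.end()) continue;
          out.push(it->second, J, s * o.r, s * o.i);
        }
      }
    }
    out.push(J, J, dre, dim_);
  }
  return out.as_list();
}

static inline double eri_at(const NumericVector &eri, int n, int i, int j,
                            int k, int l) {
  return eri[((i * n + j) * n + k) * n + l];
}

// Sparse matrix (triplets) of the full Hamiltonian by Slater-Condon rules.
//  t2n : complex one-body matrix over spin orbitals (spin-free h1 plus the
//        spin-orbit term contracted with the spin-1/2 matrices)
//  eri : spin-free two-electron integrals, chemist notation (ij|kl), flat
//        n^4 array, full (not symmetry-packed)
// Excitations leaving the determinant list (the RAS constraints) are dropped:
// this *is* the projected RAS Hamiltonian.
// [[Rcpp::export]]
List cpp_build_hamiltonian(NumericVector dets, int n_orb, ComplexMatrix t2n,
                           NumericVector eri, double e_core, bool two_body) {
  int n_spin = 2 * n_orb;
  DetMap map = build_map(dets);
  TripletSink out;
  int nd = dets.size();
  std::vector<int> occ, vir;
  occ.reserve(n_spin);
  vir.reserve(n_spin);
  for (int J = 0; J < nd; ++J) {
    uint64_t D = as_word(dets[J]);
    occ.clear();
    vir.clear();
    for (int p = 0; p < n_spin; ++p)
      ((D >> p & 1ULL) ? occ : vir).push_back(p);
    int nocc = occ.size();

    // diagonal
    double dre = e_core, dim_ = 0.0;
    for (int a = 0; a < nocc; ++a) {
      int p = occ[a];
      dre += t2n(p, p).r;
      dim_ += t2n(p, p).i;
    }
    if (two_body) {
      for (int a = 0; a < nocc; ++a) {
        int p = occ[a], pb = p % n_orb, ps = p / n_orb;
        for (int b = a + 1; b < nocc; ++b) {
          int q = occ[b], qb = q % n_orb, qs = q / n_orb;
          double v = eri_at(eri, n_orb, pb, pb, qb, qb);
          if (ps == qs) v -= eri_at(eri, n_orb, pb, qb, qb, pb);
          dre += v;
        }
      }
    }
    out.push(J, J, dre, dim_);

    // single excitations p -> r
    for (int a = 0; a < nocc; ++a) {
      int p = occ[a], pb = p % n_orb, ps = p / n_orb;
      for (size_t bv = 0; bv < vir.size(); ++bv) {
        int r = vir[bv], rb = r % n_orb, rs = r / n_orb;
        Rcomplex tv = t2n(r, p);
        double vre = tv.r, vim = tv.i;
        if (two_body && rs == ps) {
          double acc = 0.0;
          for (int c = 0; c < nocc; ++c) {
            int q = occ[c];
            if (q == p) continue;
            int qb = q % n_orb, qs = q / n_orb;
            acc += eri_at(eri, n_orb, rb, pb, qb, qb);
            if (qs == ps) acc -= eri_at(eri, n_orb, rb, qb, qb, pb);
          }
          vre += acc;
        }
        if (vre == 0.0 && vim == 0.0) continue;
        uint64_t w = D;
        bool ok = true;
        int s = annihilate(w, p, ok);
        s *= create(w, r, ok);
        DetMap::const_iterator it = map.find(w);
        if (it == map.end()) continue;
        out.push(it->second, J, s * vre, s * vim);
      }
    }

    // double excitations {p<q} -> {r<s}: <D'|H|D> = sign * [<rs|pq> - <rs|qp>]
    if (two_body) {
      for (int a = 0; a < nocc; ++a) {
        int p = occ[a], pb = p % n_orb, ps = p / n_orb;
        for (int b = a + 1; b < nocc; ++b) {
          int q = occ[b], qb = q % n_orb, qs = q / n_orb;
          for (size_t cv = 0; cv < vir.size(); ++cv) {
            int r = vir[cv], rb = r % n_orb, rs_ = r / n_orb;
            for (size_t dv = cv + 1; dv < vir.size(); ++dv) {
              int s_ = vir[dv], sb = s_ % n_orb, ss = s_ / n_orb;
              double v = 0.0;
              if (rs_ == ps && ss == qs)
                v += eri_at(eri, n_orb, rb, pb, sb, qb);
              if (rs_ == qs && ss == ps)
                v -= eri_at(eri, n_orb, rb, qb, sb, pb);
              if (v == 0.0) continue;
              uint64_t w = D;
              bool ok = true;
              int sg = annihilate(w, p, ok);
              sg *= annihilate(w, q, ok);
              sg *= create(w, s_, ok);
              sg *= create(w, r, ok);
              DetMap::const_iterator it = map.find(w);
              if (it == map.end()) continue;
              out.push(it->second, J, sg * v, 0.0);
            }
          }
        }
      }
    }
  }
  return out.as_list();
}

// Spin-summed one-particle reduced density matrix gamma[r,p] = <Psi| sum_s
// a+_{rs} a_{ps} |Psi> over spatial orbitals (complex Hermitian).
// [[Rcpp::export]]
ComplexMatrix cpp_rdm1(NumericVector dets, int n_orb, ComplexVector amp) {
  int n_spin = 2 * n_orb;
  DetMap map = build_map(dets);
  ComplexMatrix g(n_orb, n_orb);
  for (int J = 0; J < dets.size(); ++J) {
    uint64_t D = as_word(dets[J]);
    Rcomplex aJ = amp[J];
    for (int p = 0; p < n_spin; ++p) {
      if (!(D >> p & 1ULL)) continue;
      int pb = p % n_orb, ps = p / n_orb;
      for (int rb = 0; rb < n_orb; ++rb) {
        int r = ps * n_orb + rb;
        if (r == p) {
          g(pb, pb).r += aJ.r * aJ.r + aJ.i * aJ.i;
          continue;
        }
        if (D >> r & 1ULL) continue;
        uint64_t w = D;
        bool ok = true;
        int s = annihilate(w, p, ok);
        s *= create(w, r, ok);
        DetMap::const_iterator it = map.find(w);
        if (it == map.end()) continue;
        Rcomplex aI = amp[it->second];
        // conj(aI) * aJ * s
        g(rb, pb).r += s * (aI.r * aJ.r + aI.i * aJ.i);
        g(rb, pb).i += s * (aI.r * aJ.i - aI.i * aJ.r);
      }
    }
  }
  return g;
}

// All single and double excitations from one determinant that stay inside
// the space.  Returns 1-based spin-orbital indices; annih2/create2 are NA
// for singles.
// [[Rcpp::export]]
List cpp_connections(double det, NumericVector dets, int n_spin) {
  DetMap map = build_map(dets);
  uint64_t D = as_word(det);
  std::vector<int> occ, vir;
  for (int p = 0; p < n_spin; ++p)
    ((D >> p & 1ULL) ? occ : vir).push_back(p);
  std::vector<int> idx, sgn, c1, a1, c2, a2;
  for (size_t a = 0; a < occ.size(); ++a) {
    int p = occ[a];
    for (size_t bv = 0; bv < vir.size(); ++bv) {
      int r = vir[bv];
      uint64_t w = D;
      bool ok = true;
      int s = annihilate(w, p, ok);
      s *= create(w, r, ok);
      DetMap::const_iterator it = map.find(w);
      if (it == map.end()) continue;
      idx.push_back(it->second + 1);
      sgn.push_back(s);
      a1.push_back(p + 1);
      c1.push_back(r + 1);
      a2.push_back(NA_INTEGER);
      c2.push_back(NA_INTEGER);
    }
  }
  for (size_t a = 0; a < occ.size(); ++a) {
    int p = occ[a];
    for (size_t b = a + 1; b < occ.size(); ++b) {
      int q = occ[b];
      for (size_t cv = 0; cv < vir.size(); ++cv) {
        int r = vir[cv];
        for (size_t dv = cv + 1; dv < vir.size(); ++dv) {
          int s_ = vir[dv];
          uint64_t w = D;
          bool ok = true;
          int sg = annihilate(w, p, ok);
          sg *= annihilate(w, q, ok);
          sg *= create(w, s_, ok);
          sg *= create(w, r, ok);
          DetMap::const_iterator it = map.find(w);
          if (it == map.end()) continue;
          idx.push_back(it->second + 1);
          sgn.push_back(sg);
          a1.push_back(p + 1);
          c1.push_back(r + 1);
          a2.push_back(q + 1);
          c2.push_back(s_ + 1);
        }
      }
    }
  }
  return List::create(_["index"] = wrap(idx), _["sign"] = wrap(sgn),
                      _["annihilate1"] = wrap(a1), _["create1"] = wrap(c1),
                      _["annihilate2"] = wrap(a2), _["create2"] = wrap(c2));
}
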