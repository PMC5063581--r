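// Special-function kernel for the colored-noise LIF linear response.
//
// The population transfer function requires the parabolic cylinder function
// U(a, z) with complex order a = -1/2 + i*omega*tau_m and real argument z.
// No installed R package evaluates U at complex order, so it is implemented
// here via the confluent-hypergeometric representation (DLMF 12.4.1):
//
//   U(a,z) = A(a) u1(a,z) - B(a) u2(a,z)
//   u1 = exp(-z^2/4) M(a/2 + 1/4, 1/2, z^2/2)
//   u2 = z exp(-z^2/4) M(a/2 + 3/4, 3/2, z^2/2)
//   A  = sqrt(pi) 2^(-1/4 - a/2) / Gamma(3/4 + a/2)
//   B  = sqrt(pi) 2^(+1/4 - a/2) / Gamma(1/4 + a/2)
//
// For large |Im a| and |z| the Kummer series and the two-term combination
// cancel catastrophically (the intermediate terms exceed the result by a
// factor ~ exp(2 sqrt(|a| z^2/2) + z^2/2)). The evaluation is therefore
// templated on the floating type: long double for the benign region and
// GCC __float128 (about 33 significant digits) when the estimated digit
// loss would spoil double-precision output. The gamma function is
// computed by Stirling's series after argument shifting, which retains
// full precision in both branches.

#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <quadmath.h>

// ---- minimal complex arithmetic templated over long double / __float128

template <typename T> struct tmath;

template <> struct tmath<long double> {
    static long double exp(long double x) { return expl(x); }
    static long double log(long double x) { return logl(x); }
    static long double sin(long double x) { return sinl(x); }
    static long double cos(long double x) { return cosl(x); }
    static long double atan2(long double y, long double x) {
        return atan2l(y, x);
    }
    static long double sqrt(long double x) { return sqrtl(x); }
    static long double hypot(long double x, long double y) {
        return hypotl(x, y);
    }
    static constexpr long double eps() { return 1e-20L; }
};

template <> struct tmath<__float128> {
    static __float128 exp(__float128 x) { return expq(x); }
    static __float128 log(__float128 x) { return logq(x); }
    static __float128 sin(__float128 x) { return sinq(x); }
    static __float128 cos(__float128 x) { return cosq(x); }
    static __float128 atan2(__float128 y, __float128 x) {
        return atan2q(y, x);
    }
    static __float128 sqrt(__float128 x) { return sqrtq(x); }
    static __float128 hypot(__float128 x, __float128 y) {
        return hypotq(x, y);
    }
    static constexpr __float128 eps() { return 1e-34Q; }
};

template <typename T>
struct cx {
    T re, im;
    cx() : re(0), im(0) {}
    cx(T r) : re(r), im(0) {}
    cx(T r, T i) : re(r), im(i) {}
    cx operator+(const cx& o) const { return cx(re + o.re, im + o.im); }
    cx operator-(const cx& o) const { return cx(re - o.re, im - o.im); }
    cx operator*(const cx& o) const {
        return cx(re * o.re - im * o.im, re * o.im + im * o.re);
    }
    cx operator/(const cx& o) const {
        T d = o.re * o.re + o.im * o.im;
        return cx((re * o.re + im * o.im) / d,
                  (im * o.re - re * o.im) / d);
    }
    cx operator-() const { return cx(-re, -im); }
};

template <typename T> T cabs2(const cx<T>& z) {
    return z.re * z.re + z.im * z.im;
}
template <typename T> T cabs(const cx<T>& z) {
    return tmath<T>::hypot(z.re, z.im);
}
template <typename T> cx<T> cexp(const cx<T>& z) {
    T e = tmath<T>::exp(z.re);
    return cx<T>(e * tmath<T>::cos(z.im), e * tmath<T>::sin(z.im));
}
template <typename T> cx<T> clog(const cx<T>& z) {
    return cx<T>(tmath<T>::log(cabs(z)), tmath<T>::atan2(z.im, z.re));
}

static const long double PI_L = 3.141592653589793238462643383279502884L;

// log Gamma by argument shift + Stirling series (Bernoulli terms up to
// B_22; ~33-digit accurate once Re(z) >= 24)
template <typename T>
cx<T> lngamma_t(cx<T> z) {
    static const long double bern[] = {
        1.0L / 12, -1.0L / 360, 1.0L / 1260, -1.0L / 1680, 1.0L / 1188,
        -691.0L / 360360, 7.0L / 156, -3617.0L / 122400, 43867.0L / 244188,
        -174611.0L / 125400, 77683.0L / 5796 };
    cx<T> shift(0);
    int nshift = 0;
    while (z.re < (T)24 && nshift < 64) {
        shift = shift + clog(z);
        z = z + cx<T>(1);
        ++nshift;
    }
    cx<T> zi = cx<T>(1) / z, zi2 = zi * zi, acc(0), p = zi;
    for (int k = 0; k < 11; ++k) {
        acc = acc + p * cx<T>((T)bern[k]);
        p = p * zi2;
    }
    cx<T> half_log2pi((T)(0.5L * logl(2.0L * PI_L)));
    cx<T> res = (z - cx<T>((T)0.5)) * clog(z) - z + half_log2pi + acc;
    return res - shift;
}

// Kummer's M(a, b, x), real non-negative x
template <typename T>
cx<T> kummer_t(cx<T> a, cx<T> b, T x) {
    cx<T> term(1), sum(1);
    long double abs_a = (long double)cabs(a);
    long double n_min = (long double)x +
        2.0L * sqrtl((abs_a + 1.0L) * (long double)x) + 10.0L;
    const int n_max = 200000;
    T eps = tmath<T>::eps();
    for (int n = 0; n < n_max; ++n) {
        term = term * ((a + cx<T>((T)n)) / (b + cx<T>((T)n)))
             * cx<T>(x / (T)(n + 1));
        sum = sum + term;
        if ((long double)(n + 1) > n_min &&
            cabs2(term) < eps * eps * cabs2(sum)) break;
    }
    return sum;
}

// U(a, z) via DLMF 12.4.1
template <typename T>
cx<T> pcf_u_t(cx<T> a, T z) {
    T x2h = (T)0.5 * z * z;
    cx<T> ez = cexp(cx<T>(-(T)0.5 * x2h));
    cx<T> u1 = ez * kummer_t(a * cx<T>((T)0.5) + cx<T>((T)0.25),
                             cx<T>((T)0.5), x2h);
    cx<T> u2 = cx<T>(z) * ez *
        kummer_t(a * cx<T>((T)0.5) + cx<T>((T)0.75), cx<T>((T)1.5), x2h);
    T lsp = (T)(0.5L * logl(PI_L)), l2 = (T)logl(2.0L);
    cx<T> A = cexp(cx<T>(lsp) - (cx<T>((T)0.25) + a * cx<T>((T)0.5)) * cx<T>(l2)
                   - lngamma_t(cx<T>((T)0.75) + a * cx<T>((T)0.5)));
    cx<T> B = cexp(cx<T>(lsp) + (cx<T>((T)0.25) - a * cx<T>((T)0.5)) * cx<T>(l2)
                   - lngamma_t(cx<T>((T)0.25) + a * cx<T>((T)0.5)));
    return A * u1 - B * u2;
}

// estimated decimal digits lost to cancellation: Kummer series peak
// ~ exp(2 sqrt(|a/2| z^2/2)) and, on the decaying side (z > 0), the
// two-solution combination ~ exp(z^2/2)
static double digit_loss(double a_re, double a_im, double z) {
    double x2h = 0.5 * z * z;
    double abs_a2 = 0.5 * std::hypot(a_re, a_im);
    double loss = 2.0 * std::sqrt((abs_a2 + 1.0) * x2h);
    if (z > 0) loss += x2h;
    return loss / std::log(10.0);
}

static std::complex<double> pcf_u_any(std::complex<double> a, double z) {
    double loss = digit_loss(a.real(), a.imag(), z);
    if (loss < 8.0) {
        cx<long double> al((long double)a.real(), (long double)a.imag());
        cx<long double> r = pcf_u_t(al, (long double)z);
        return std::complex<double>((double)r.re, (double)r.im);
    }
    cx<__float128> aq((__float128)a.real(), (__float128)a.imag());
    cx<__float128> r = pcf_u_t(aq, (__float128)z);
    return std::complex<double>((double)r.re, (double)r.im);
}

//' @noRd
// [[Rcpp::export]]
Rcpp::ComplexVector cpp_pcf_u(Rcpp::ComplexVector a, Rcpp::NumericVector z) {
    R_xlen_t n = a.size();
    if (z.size() != n) Rcpp::stop("length mismatch between 'a' and 'z'");
    Rcpp::ComplexVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        std::complex<double> val =
            pcf_u_any(std::complex<double>(a[k].r, a[k].i), z[k]);
        out[k].r = val.real();
        out[k].i = val.imag();
    }
    return out;
}

// Phi(a, x) = exp(x^2/4) U(a, -x); the exponential is folded into the
// high-precision branch so the product survives intermediate overflow
//' @noRd
// [[Rcpp::export]]
Rcpp::ComplexVector cpp_pcf_phi(Rcpp::ComplexVector a, Rcpp::NumericVector x) {
    R_xlen_t n = a.size();
    if (x.size() != n) Rcpp::stop("length mismatch between 'a' and 'x'");
    Rcpp::ComplexVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        std::complex<double> u =
            pcf_u_any(std::complex<double>(a[k].r, a[k].i), -x[k]);
        double e = std::exp(0.25 * x[k] * x[k]);
        out[k].r = e * u.real();
        out[k].i = e * u.imag();
    }
    return out;
}
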