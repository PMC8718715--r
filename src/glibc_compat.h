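// The build toolchain targets a newer glibc than some runtime systems
// provide; a few libm entry points were re-versioned in glibc 2.38.
// Pin them to their long-stable versions so the shared object also loads
// against older glibc runtimes.
#ifndef ROTORMAP_GLIBC_COMPAT_H
#define ROTORMAP_GLIBC_COMPAT_H
#if defined(__linux__) && defined(__x86_64__) && defined(__GNUC__)
__asm__(".symver fmod,fmod@GLIBC_2.2.5");
__asm__(".symver fmodf,fmodf@GLIBC_2.2.5");
#endif
#endif
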