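{
  "language": "es",
  "menu": {
    "prompt": "¡Hola, soy Wakamola {emoji:wave}! ¿Qué quieres hacer?\n1. Personal\n2. Dieta\n3. Actividad\n4. Wakanet (comparte con tus contactos)\n5. Wakastatus (tus puntuaciones)\n6. Acerca de\nResponde con un número del 1 al 6."
  },
  "strings": {
    "invalid_choice": "No te he entendido. Responde con una de las opciones indicadas.",
    "invalid_number": "Responde con un número entre {min} y {max}.",
    "invalid_boolean": "Responde sí o no.",
    "section_complete": "¡Genial, la sección {section} está completa! {emoji:party}",
    "already_complete": "Ya has completado esa sección. Reiníciala explícitamente si quieres cambiar tus respuestas.",
    "assessment_complete": "Has completado todas las secciones. ¡Consulta tu Wakastatus desde el menú!",
    "not_ready": "Completa primero las secciones Personal, Dieta y Actividad."
  },
  "sections": {
    "personal": {
      "title": "Personal",
      "questions": {
        "weight": { "prompt": "¿Cuál es tu peso en kilogramos?" },
        "height": { "prompt": "¿Cuál es tu estatura en metros (p. ej. 1,75)?" },
        "gender": { "prompt": "¿Cuál es tu género? (female / male / other)" },
        "age": { "prompt": "¿Cuántos años tienes?" },
        "education_level": { "prompt": "¿Cuál es tu nivel de estudios? (primary / secondary / university / postgraduate)" },
        "marital_status": { "prompt": "¿Cuál es tu estado civil? (single / partner / married / other)" },
        "household_size": { "prompt": "¿Cuántas personas viven en tu casa, incluida tú?" },
        "main_activity": { "prompt": "¿Cuál es tu actividad principal? (study / work / other)" },
        "zip_code": { "prompt": "¿Cuál es tu código postal?" },
        "sleep_hours": { "prompt": "¿Cuántas horas duermes al día?" },
        "cigarettes": { "prompt": "¿Cuántos cigarrillos fumas al día?" },
        "dx_hypertension": { "prompt": "¿Te han diagnosticado (o tomas medicación para) hipertensión? (sí/no)" },
        "dx_diabetes": { "prompt": "¿Te han diagnosticado (o tomas medicación para) diabetes? (sí/no)" },
        "dx_cholesterol": { "prompt": "¿Te han diagnosticado (o tomas medicación para) colesterol alto? (sí/no)" },
        "dx_cardiovascular": { "prompt": "¿Te han diagnosticado (o tomas medicación para) enfermedad cardiovascular? (sí/no)" }
      }
    },
    "diet": {
      "title": "Dieta",
      "item_prompt": "¿Con qué frecuencia consumes {item}? {emoji:apple}\n1. Nunca\n2. Menos de una vez a la semana\n3. 1-2 veces a la semana\n4. 3-6 veces a la semana\n5. Una vez al día\n6. Dos o más veces al día",
      "reprompt": "Responde con un número del 1 al 6."
    },
    "activity": {
      "title": "Actividad",
      "questions": {
        "vigorous_days": { "prompt": "En los últimos 7 días, ¿cuántos días hiciste actividad física vigorosa? (0-7)" },
        "vigorous_minutes": { "prompt": "¿Cuántos minutos solías dedicar a la actividad vigorosa en uno de esos días?" },
        "moderate_days": { "prompt": "En los últimos 7 días, ¿cuántos días hiciste actividad física moderada? (0-7)" },
        "moderate_minutes": { "prompt": "¿Cuántos minutos solías dedicar a la actividad moderada en uno de esos días?" },
        "walk_days": { "prompt": "En los últimos 7 días, ¿cuántos días caminaste al menos 10 minutos seguidos? (0-7)" },
        "walk_minutes": { "prompt": "¿Cuántos minutos solías caminar en uno de esos días?" },
        "sitting_hours": { "prompt": "¿Cuántas horas a la semana pasas sentado/a?" }
      }
    },
    "wakanet": {
      "title": "Wakanet",
      "intro": "Comparte Wakamola con tus contactos para construir tu red {emoji:muscle}. Tienes {n_contacts} contactos.",
      "invite_messages": {
        "home": "¡Únete a Wakamola! Invitación para las personas con las que vivo: {token}",
        "family": "¡Únete a Wakamola! Invitación para mi familia: {token}",
        "friend": "¡Únete a Wakamola! Invitación para mis amistades: {token}",
        "work": "¡Únete a Wakamola! Invitación para mis colegas de trabajo: {token}"
      }
    },
    "wakastatus": {
      "title": "Wakastatus",
      "status_message": "Aquí tienes tu estado {emoji:smile}\nWakastatus: {wakastatus}/100\nDieta (Wakalimentation): {diet_score}\nActividad: {activity_score}\nWakaBMI: {bmi_score}\nRed social (Wakasocial): {social_score}\nCategoría de IMC: {bmi_category}\n¡Cuanto más alto mejor: meta 100!"
    },
    "about": {
      "title": "Acerca de",
      "text": "Wakamola te ayuda a evaluar tu dieta, actividad física, IMC y red social, y te da una puntuación global de estado de 0 a 100."
    }
  },
  "emoji": {
    "wave": "👋",
    "party": "🎉",
    "apple": "🍎",
    "muscle": "💪",
    "smile": "🙂"
  }
}
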